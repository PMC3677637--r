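#' Strain panel
#'
#' The seven-strain panel used throughout (wild type plus the classical
#' HOG-pathway perturbations); the single deletions `pfk26`Δ and
#' `pfk27`Δ are also available in [strain_spec()].
#'
#' @return Character vector of strain names.
#' @export
hog_strains <- function() {
  c("WT", "gpd1Δ", "pfk26/27Δ", "FPS1-Δ1", "stl1Δ",
    "hog1Δ", "HOG1-att")
}

all_strain_names <- function() {
  c(hog_strains(), "pfk26Δ", "pfk27Δ")
}

# accept ASCII aliases so the package is usable from plain-ASCII scripts
canonical_strain <- function(name) {
  aliases <- c(
    "WT" = "WT", "wt" = "WT",
    "hog1d" = "hog1Δ", "hog1D" = "hog1Δ",
    "gpd1d" = "gpd1Δ", "gpd1D" = "gpd1Δ",
    "pfk26d" = "pfk26Δ", "pfk27d" = "pfk27Δ",
    "pfk26/27d" = "pfk26/27Δ", "pfk2627d" = "pfk26/27Δ",
    "HOG1-att" = "HOG1-att", "hog1-att" = "HOG1-att",
    "FPS1-D1" = "FPS1-Δ1", "fps1-D1" = "FPS1-Δ1",
    "fps1-d1" = "FPS1-Δ1",
    "stl1d" = "stl1Δ", "stl1D" = "stl1Δ"
  )
  if (name %in% all_strain_names()) return(name)
  if (name %in% names(aliases)) return(unname(aliases[[name]]))
  stop("unknown strain: ", name, " (known: ",
       paste(all_strain_names(), collapse = ", "), ")", call. = FALSE)
}

#' Build a strain specification
#'
#' Encodes the known genetic effect of each perturbation as absolute
#' parameter overrides of the shared wild-type parameter set (so that
#' applying a spec is idempotent), plus states pinned by the genotype:
#' \itemize{
#' \item `hog1`Δ: `Hog1tot = 0` (no kinase, no phospho-pool);
#' \item `gpd1`Δ: `k_b1 = k_h1 = k_o1 = 0` (no GPD1 transcription);
#' \item `pfk26/27`Δ: `PfkT = 0`; single deletions halve `PfkT`;
#' \item `HOG1-att` (membrane-anchored Hog1): `k_h1 = k_s1 = 0` (no
#'   transcriptional output), Fps1 closure gain `k_cH` multiplied by
#'   `att_gain`, Pfk26/27 activation retained;
#' \item `FPS1-`Δ1: the channel cannot close (`k_cT = k_cH =
#'   k_open = 0`, `Fps1o` pinned at 1);
#' \item `stl1`Δ: `VmSTL = 0`.
#' }
#'
#' @param name Strain name (canonical or ASCII alias, e.g. `"hog1d"`).
#' @param ref Wild-type reference parameters the overrides are computed
#'   from.
#' @param att_gain Fold-increase of the Hog1-dependent Fps1 closure rate
#'   in `HOG1-att` (membrane proximity of the anchored kinase).
#' @return An object of class `hog_strain` with fields `name`, `edits`
#'   (named numeric overrides) and `pinned_states`.
#' @export
strain_spec <- function(name, ref = hog_params(), att_gain = 2) {
  nm <- canonical_strain(name)
  edits <- numeric(0)
  pinned <- numeric(0)
  D <- "Δ"
  if (nm == paste0("hog1", D)) {
    edits <- c(Hog1tot = 0)
  } else if (nm == paste0("gpd1", D)) {
    edits <- c(k_b1 = 0, k_h1 = 0, k_o1 = 0)
  } else if (nm == paste0("pfk26/27", D)) {
    edits <- c(PfkT = 0)
  } else if (nm %in% paste0(c("pfk26", "pfk27"), D)) {
    edits <- c(PfkT = unname(ref[["PfkT"]]) * 0.5)
  } else if (nm == "HOG1-att") {
    edits <- c(k_h1 = 0, k_s1 = 0,
               k_cH = unname(ref[["k_cH"]]) * att_gain)
  } else if (nm == paste0("FPS1-", D, "1")) {
    edits <- c(k_cT = 0, k_cH = 0, k_open = 0)
    pinned <- c(Fps1o = 1)
  } else if (nm == paste0("stl1", D)) {
    edits <- c(VmSTL = 0)
  }
  bad <- setdiff(names(edits), hog_param_names())
  if (length(bad)) stop("edit references unknown parameter: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = nm, edits = edits, pinned_states = pinned),
            class = "hog_strain")
}

#' @export
print.hog_strain <- function(x, ...) {
  cat("<hog_strain> ", x$name, "\n", sep = "")
  if (length(x$edits)) {
    cat("  edits: ", paste(names(x$edits), "=", signif(x$edits, 4),
                           collapse = ", "), "\n", sep = "")
  } else cat("  edits: none\n")
  if (length(x$pinned_states)) {
    cat("  pinned: ", paste(names(x$pinned_states), "=", x$pinned_states,
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Apply a strain specification to a parameter set
#'
#' Returns an edited copy of `params` (the input is never modified) with
#' the spec's absolute overrides in place; applying the same spec twice
#' is a no-op.
#'
#' @param params A `hog_params` vector (typically the wild-type set).
#' @param spec A `hog_strain` object or a strain name.
#' @return A `hog_params` vector with attribute `pinned_states`.
#' @export
apply_strain <- function(params, spec) {
  if (is.character(spec)) spec <- strain_spec(spec, ref = params)
  stopifnot(inherits(spec, "hog_strain"))
  out <- unclass(params)
  if (length(spec$edits)) out[names(spec$edits)] <- spec$edits
  structure(out, class = c("hog_params", "numeric"),
            pinned_states = spec$pinned_states, strain = spec$name)
}
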