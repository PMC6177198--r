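#' Generate the standard aspiration fixture files
#'
#' Writes reproducible per-individual aspiration CSVs (100 individuals each)
#' for the distributions used across the simulation studies: two independent
#' sets from uniform `[0, 1]`, two from uniform `[0, 5]`, the homogeneous
#' level `e = 2`, the bimodal normal mixture, and the power law
#' `f(x) = 2 x^{-3}`. Regeneration with the same seed is byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n Number of individuals per file.
#' @return Character vector of the 7 file paths written, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, n = 100L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- list(
    uniform01_set1 = function() sample_aspirations(n, "uniform", lo = 0, hi = 1),
    uniform01_set2 = function() sample_aspirations(n, "uniform", lo = 0, hi = 1),
    uniform05_set1 = function() sample_aspirations(n, "uniform", lo = 0, hi = 5),
    uniform05_set2 = function() sample_aspirations(n, "uniform", lo = 0, hi = 5),
    homogeneous2   = function() sample_aspirations(n, "homogeneous", value = 2),
    bimodal        = function() sample_aspirations(n, "bimodal"),
    powerlaw       = function() sample_aspirations(n, "powerlaw")
  )
  set.seed(seed)
  paths <- character(0)
  for (nm in names(specs)) {
    prof <- specs[[nm]]()
    path <- file.path(out_dir, paste0("aspirations_", nm, ".csv"))
    save_aspirations(prof, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
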