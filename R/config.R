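#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline in one list. Values may be
#' overridden individually via `...` or loaded from a YAML file with
#' [read_config()].
#'
#' @param ... named overrides of any default field.
#'
#' @return A named list with fields:
#' \describe{
#'   \item{expression_median_min}{abundance filter: minimum group median TPM
#'     (default 0.5).}
#'   \item{expression_max_min}{abundance filter: minimum group maximum TPM
#'     (default 1.0).}
#'   \item{entropy_variable_percentile}{normalized-entropy percentile at or
#'     above which a gene counts as highly variable/stably expressed for PCA
#'     (default 0.90).}
#'   \item{entropy_nonubiquitous_percentile}{percentile below which an
#'     expressed gene is retained for DE testing (default 0.75).}
#'   \item{alpha}{per-level BH FDR threshold (default 0.05).}
#'   \item{fold_threshold}{minimum quantile fold change for a DE call
#'     (default 1.2).}
#'   \item{epsilon}{SSMD smoothing factor (default 0.001).}
#'   \item{fold_pseudo}{pseudo-quantity added to both quantiles in fold
#'     computation to guard against zeros (default 0.001).}
#'   \item{fold_gate}{"own" gates each test level on the fold at its own
#'     quantile; "median" gates both on the median fold.}
#'   \item{outlier_sd}{standardized distance at which a sample is flagged as
#'     a PCA outlier (default 2.0).}
#'   \item{outlier_components}{number of leading components used for outlier
#'     distance (default 2).}
#'   \item{outlier_standardize}{divide each component score by its standard
#'     deviation before computing the distance (default TRUE).}
#'   \item{r_threshold}{absolute Pearson R above which an age correlation can
#'     be called significant (default 0.20).}
#'   \item{pca_log2}{log2(TPM + 1) transform before PCA (default TRUE).}
#'   \item{pca_standardize}{per-gene standardization before PCA (default TRUE).}
#'   \item{age_range}{plausible donor age range in years (default c(21, 70)).}
#' }
#' @export
#' @examples
#' cfg <- pipeline_config(alpha = 0.01)
#' cfg$alpha
pipeline_config <- function(...) {
  cfg <- list(
    expression_median_min = 0.5,
    expression_max_min = 1.0,
    entropy_variable_percentile = 0.90,
    entropy_nonubiquitous_percentile = 0.75,
    alpha = 0.05,
    fold_threshold = 1.2,
    epsilon = 0.001,
    fold_pseudo = 0.001,
    fold_gate = "own",
    outlier_sd = 2.0,
    outlier_components = 2L,
    outlier_standardize = TRUE,
    r_threshold = 0.20,
    pca_log2 = TRUE,
    pca_standardize = TRUE,
    age_range = c(21, 70)
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(override)] <- override
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$fold_threshold >= 1,
    cfg$epsilon > 0,
    cfg$fold_pseudo > 0,
    cfg$fold_gate %in% c("own", "median"),
    cfg$entropy_variable_percentile > 0, cfg$entropy_variable_percentile <= 1,
    cfg$entropy_nonubiquitous_percentile > 0,
    cfg$entropy_nonubiquitous_percentile <= 1,
    cfg$outlier_sd > 0,
    cfg$outlier_components >= 1,
    cfg$r_threshold >= 0, cfg$r_threshold < 1,
    length(cfg$age_range) == 2, cfg$age_range[1] < cfg$age_range[2]
  )
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Fields present in the file override the [pipeline_config()] defaults; a
#' `simulation:` block, if present, overrides [simulation_config()] defaults
#' and is returned in the `simulation` element.
#'
#' @param path path to a YAML file.
#' @return A configuration list as from [pipeline_config()], with an optional
#'   `simulation` element.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- do.call(simulation_config, raw$simulation)
    raw$simulation <- NULL
  }
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(sim)) cfg$simulation <- sim
  cfg
}
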