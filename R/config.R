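#' Pipeline configuration
#'
#' Bundles every tunable of the decoding pipeline. Defaults follow the
#' 32-channel, 6-target protocol: the nine-channel parieto-occipital set as
#' signal channels, every other channel as reference, a 4-45 Hz zero-phase
#' band-pass (use [band_preset_narrow()] for the stricter 4-30 Hz band), no
#' decimation, RLS enhancement on, three reference harmonics, and
#' leave-one-block-out folds.
#'
#' @param occ_names occipital channel names (default [occipital_9()]).
#' @param nonocc_names non-occipital channel names; `NULL` means "all other
#'   channels of the tensor" resolved at run time.
#' @param band a [band_spec()].
#' @param decimate_factor integer decimation factor (1 = keep rate).
#' @param car_scope `"nonoccipital"`: the non-occipital mean only serves as
#'   the adaptive reference; `"all"`: additionally re-reference all channels
#'   to the whole-head common average before splitting.
#' @param rls_enabled logical; `FALSE` gives the pure-CCA baseline.
#' @param rls an [rls_params()].
#' @param n_harmonics,ridge CCA template harmonics and regularisation.
#' @param window_start_s,window_length_s epoch window inside each trial
#'   (`NULL` length = full trial).
#' @param k_folds number of block folds; `NULL` means leave-one-block-out.
#' @param selection_s seconds per selection T used for the ITR. There is no
#'   universal default in the literature (it depends on gaze-shift time);
#'   4 s is used unless configured.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(occ_names = occipital_9(), nonocc_names = NULL,
                            band = band_spec(), decimate_factor = 1,
                            car_scope = c("nonoccipital", "all"),
                            rls_enabled = TRUE, rls = rls_params(),
                            n_harmonics = 3, ridge = 1e-8,
                            window_start_s = 0, window_length_s = NULL,
                            k_folds = NULL, selection_s = 4) {
  car_scope <- match.arg(car_scope)
  stopifnot(inherits(band, "band_spec"), inherits(rls, "rls_params"))
  structure(
    list(occ_names = occ_names, nonocc_names = nonocc_names, band = band,
         decimate_factor = as.integer(decimate_factor),
         car_scope = car_scope, rls_enabled = isTRUE(rls_enabled), rls = rls,
         n_harmonics = as.integer(n_harmonics), ridge = ridge,
         window_start_s = window_start_s, window_length_s = window_length_s,
         k_folds = k_folds, selection_s = selection_s),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys mirror the arguments of [pipeline_config()], with nested
#' groups `band` (`low`, `high`, `order`), `rls` (`taps`, `forgetting`,
#' `init_scale`, `enabled`), `cca` (`n_harmonics`, `ridge`), `car`
#' (`scope`), `decimate` (`factor`) and `window` (`start_s`, `length_s`).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- read_config_file(path)
  band <- band_spec(raw$band$low %||% 4, raw$band$high %||% 45,
                    raw$band$order %||% 4)
  rls <- rls_params(raw$rls$taps %||% 8, raw$rls$forgetting %||% 0.999,
                    raw$rls$init_scale %||% 0.01)
  pipeline_config(
    occ_names = raw$occ_names %||% occipital_9(),
    nonocc_names = raw$nonocc_names,
    band = band,
    decimate_factor = raw$decimate$factor %||% 1,
    car_scope = raw$car$scope %||% "nonoccipital",
    rls_enabled = raw$rls$enabled %||% TRUE,
    rls = rls,
    n_harmonics = raw$cca$n_harmonics %||% 3,
    ridge = raw$cca$ridge %||% 1e-8,
    window_start_s = raw$window$start_s %||% 0,
    window_length_s = raw$window$length_s,
    k_folds = raw$k_folds,
    selection_s = raw$selection_s %||% 4
  )
}

#' Read a simulation scenario from YAML or JSON
#'
#' Keys mirror the arguments of [sim_scenario()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_scenario()].
#' @export
read_sim_scenario <- function(path) {
  raw <- read_config_file(path)
  defaults <- formals(sim_scenario)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_scenario, raw)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON, got .", ext, call. = FALSE)
  }
}
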