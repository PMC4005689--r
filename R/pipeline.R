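## End-to-end pipeline: barcode-level fragment tables -> per-library barcode
## model and EUCs -> reactivity profile -> outputs.

#' Default run configuration
#'
#' All tunables with their standard values: 7-nt barcode, 100-nt minimum span
#' and minimum priming distance for random-primed libraries (0 in
#' single-primer mode), 3-nt smoothing window offset 1 position upstream, 0.9
#' detection probability for the coverage cutoff, 14-A contact radius, 1.4-A
#' water probe (3.0 A is the wide-probe alternative used for large rRNA).
#'
#' @param mode `"random"` (random-primed, size-selected) or `"single"`
#'   (one 3' primer).
#' @param ... overrides of individual fields.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("random", "single"), ...) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, barcode_length = 7L,
              min_span = if (mode == "random") 100L else 0L,
              min_priming_distance = if (mode == "random") 100L else 0L,
              max_trim = 3L, window = 3L, offset_upstream = 1L,
              detection_prob = 0.9, contact_radius = 14,
              probe_radius = 1.4, dot_density = 3L, seed = 1L,
              region = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Serialise / parse a run configuration (lossless round trip)
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$region <- if (length(cfg$region)) as.integer(cfg$region) else NULL
  int_fields <- c("barcode_length", "min_span", "min_priming_distance",
                  "max_trim", "window", "offset_upstream", "dot_density",
                  "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "run_config")
}

#' Run the fragment-to-reactivity pipeline
#'
#' For each library: span filter, per-library barcode frequency estimation
#' (each ligation reaction gets its own pool estimate), barcode probabilities,
#' aggregation to fragments and EUC assignment; then the treated-minus-control
#' reactivity profile.
#'
#' @param treated,control barcode-level fragment tables (single reference).
#' @param ref_len reference length.
#' @param config a [run_config()].
#' @param out_prefix if non-`NULL`, writes `<prefix>.reactivity.tsv` (+ JSON
#'   summary sidecar), per-library EUC fragment TSVs and frequency matrices.
#' @return list with `profile` (`reactivity_profile`), per-library `euc`
#'   tables and `barcode_model`s.
#' @export
run_pipeline <- function(treated, control, ref_len, config = run_config(),
                         out_prefix = NULL) {
  stopifnot(inherits(config, "run_config"))
  region <- if (is.null(config$region)) c(1L, as.integer(ref_len))
            else as.integer(config$region)
  prep <- function(tab) {
    tab <- span_filter(tab, config$min_span)
    if (nrow(tab) == 0L) stop("no fragments survive the span filter")
    bd <- estimate_position_frequencies(tab, L = config$barcode_length)
    probs <- barcode_probabilities(bd)
    agg <- add_euc(aggregate_fragments(tab), probs)
    list(bd = bd, agg = agg)
  }
  t <- prep(treated)
  c <- prep(control)
  profile <- reactivity_profile(
    t$agg, c$agg, ref_len, region = region,
    min_priming_distance = config$min_priming_distance,
    window = config$window, offset_upstream = config$offset_upstream,
    detection_prob = config$detection_prob)
  if (!is.null(out_prefix)) {
    hash <- config_hash(unclass(config))
    extra <- c(config_hash = hash, seed = config$seed)
    write_reactivity(profile, paste0(out_prefix, ".reactivity.tsv"),
                     extra = extra)
    write_fragment_table(t$agg, paste0(out_prefix, ".treated.euc.tsv"),
                         extra = extra)
    write_fragment_table(c$agg, paste0(out_prefix, ".control.euc.tsv"),
                         extra = extra)
    write_frequency_matrix(t$bd, paste0(out_prefix, ".treated.barcode_freq.tsv"))
    write_frequency_matrix(c$bd, paste0(out_prefix, ".control.barcode_freq.tsv"))
  }
  list(profile = profile, treated_euc = t$agg, control_euc = c$agg,
       treated_barcode_model = t$bd, control_barcode_model = c$bd)
}
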