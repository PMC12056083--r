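#' Default analyte-to-node alias map
#'
#' Immunoassay panels and network models spell protein names differently
#' (e.g. `IL-6` vs `IL6`, Greek vs ASCII integrin names). The alias map is
#' an explicit two-column table mapping panel spellings to canonical network
#' node names; [align_model_experiment()] applies it before intersecting.
#'
#' @return data.frame with columns `alias` and `node`.
#' @export
default_alias_map <- function() {
  data.frame(
    alias = c("IL-6", "IL-8", "IL-17", "IL-17A", "IL-4", "IL-13", "IL-18",
              "IL-1b", "TGF-b1", "TGF-b", "IFN-g", "MMP-1", "MMP-3",
              "MMP-9", "MMP-13", "TNF-a", "\u03b15\u03b21",
              "\u03b1v\u03b23", "NF-kB"),
    node = c("IL6", "IL8", "IL17", "IL17", "IL4", "IL13", "IL18",
             "IL1B", "TGFB", "TGFB", "IFNG", "MMP1", "MMP3",
             "MMP9", "MMP13", "TNF", "a5b1", "avb3", "NFKB"),
    stringsAsFactors = FALSE)
}

apply_aliases <- function(names, alias_map) {
  if (is.null(alias_map) || !nrow(alias_map)) return(names)
  i <- match(names, alias_map$alias)
  ifelse(is.na(i), names, alias_map$node[i])
}

#' Align model predictions with calibrated secretome values
#'
#' Builds the per-condition table of paired values the concordance
#' statistics run on: for every condition, the referenced experimental value
#' `x` (median-aggregated, reference-subtracted, from
#' [aggregate_and_reference()]) and the referenced model value `y`
#' (ensemble-mean activation minus the reference condition's ensemble mean).
#' Only proteins present on both sides (after alias resolution) are kept;
#' unmatched names on either side are recorded.
#'
#' @param ensembles named list of `rnm_ensemble` objects, keyed or mapped by
#'   condition label (see [preset_condition()]); must include the reference
#'   condition.
#' @param calibrated a `calibrated_secretome`.
#' @param alias_map data.frame `alias, node` mapping panel analyte names to
#'   network node names. Default [default_alias_map()].
#' @param reference reference condition label. Default `"control_unloaded"`.
#' @return An object of class `comparison_table`: data.frame with columns
#'   `condition, protein, x, y` and attributes `n_aligned`,
#'   `unmatched_model`, `unmatched_experiment`, `alias_map`, `reference`.
#' @export
align_model_experiment <- function(ensembles, calibrated,
                                   alias_map = default_alias_map(),
                                   reference = "control_unloaded") {
  conds <- vapply(ensembles, function(e) preset_condition(e$preset), "")
  if (!is.null(names(ensembles)) && all(nzchar(names(ensembles)))) {
    conds <- names(ensembles)
  }
  if (!reference %in% conds) {
    stop("ensembles must include the reference condition '", reference, "'")
  }
  model <- vapply(ensembles, function(e) e$mean_activation,
                  ensembles[[1]]$mean_activation)
  colnames(model) <- conds
  model_ref <- model - model[, reference]

  cal <- as.data.frame(calibrated)
  cal$protein <- apply_aliases(cal$analyte, alias_map)

  nodes <- rownames(model_ref)
  shared <- intersect(nodes, unique(cal$protein))
  if (!length(shared)) {
    stop("no protein name maps between model and panel; model nodes: ",
         paste(utils::head(nodes, 10), collapse = ", "),
         " / panel analytes: ",
         paste(utils::head(unique(cal$protein), 10), collapse = ", "))
  }

  cal_conds <- intersect(conds, unique(cal$condition))
  rows <- do.call(rbind, lapply(cal_conds, function(cc) {
    sub <- cal[cal$condition == cc & cal$protein %in% shared, ]
    sub <- sub[order(sub$protein), ]
    data.frame(condition = cc, protein = sub$protein,
               x = sub$x_ref, y = model_ref[sub$protein, cc],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("comparison_table", "data.frame"),
            n_aligned = length(shared),
            unmatched_model = setdiff(nodes, shared),
            unmatched_experiment =
              setdiff(unique(cal$protein), shared),
            alias_map = alias_map, reference = reference)
}

#' Normalized mean absolute deviation (NMAD)
#'
#' Cumulative model-experiment error per condition:
#' \deqn{NMAD = \frac{\sum_n^N |x_n - y_n|}{N}}
#' over the N aligned protein pairs, reported as a percentage (x100).
#'
#' @param table a `comparison_table` (or data.frame with `condition, x, y`).
#' @param percent report x100 as percent (default) or as the raw fraction.
#' @return named numeric vector, one NMAD per condition.
#' @export
nmad <- function(table, percent = TRUE) {
  df <- as.data.frame(table)
  stopifnot(nrow(df) >= 1)
  v <- tapply(abs(df$x - df$y), df$condition, mean)
  out <- stats::setNames(as.numeric(v), names(v))
  if (percent) 100 * out else out
}

#' Per-protein normalized root squared error (NRSE)
#'
#' Per protein n, the root squared error RSE_n is scaled by the worst
#' protein's error so the maximum NRSE is 1:
#' \deqn{NRSE_n = RSE_n / MAX.RSE.}
#' Two RSE conventions are provided: `"difference"` (default),
#' \eqn{RSE_n = \sqrt{(x_n - y_n)^2} = |x_n - y_n|}, and `"as_printed"`,
#' \eqn{RSE_n = \sqrt{(x_n + y_n)^2} = |x_n + y_n|} (kept selectable; note
#' the summed form is 0 when model and experiment agree in magnitude but
#' differ in sign). `MAX.RSE` is taken per condition by default, or once
#' across all conditions with `scope = "global"`. When `MAX.RSE` is 0 all
#' NRSE are defined as 0.
#'
#' @param table a `comparison_table`.
#' @param mode `"difference"` or `"as_printed"`.
#' @param scope `"condition"` or `"global"` scaling of `MAX.RSE`.
#' @return data.frame `condition, protein, rse, nrse` with attributes
#'   `max_rse` (named per condition, or scalar for global scope) and `mode`.
#' @export
nrse <- function(table, mode = c("difference", "as_printed"),
                 scope = c("condition", "global")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  df <- as.data.frame(table)
  stopifnot(nrow(df) >= 1)
  df$rse <- if (mode == "difference") abs(df$x - df$y) else abs(df$x + df$y)
  if (scope == "global") {
    mx <- max(df$rse)
    df$nrse <- if (mx > 0) df$rse / mx else 0
    max_rse <- mx
  } else {
    mx <- tapply(df$rse, df$condition, max)
    denom <- as.numeric(mx[df$condition])
    df$nrse <- ifelse(denom > 0, df$rse / denom, 0)
    max_rse <- stats::setNames(as.numeric(mx), names(mx))
  }
  out <- df[, c("condition", "protein", "rse", "nrse")]
  structure(out, max_rse = max_rse, mode = mode, scope = scope)
}

#' Rank proteins by concordance error
#'
#' Sorts proteins by NRSE descending (aggregated across conditions by their
#' maximum NRSE when a protein appears in several), ties broken
#' alphabetically, and returns the top k.
#'
#' @param nrse_table output of [nrse()] (or any data.frame with `protein`
#'   and `nrse`).
#' @param k number of proteins to return; if `k` exceeds the number of
#'   proteins all are returned with a note attribute.
#' @return character vector of protein names, worst first, with the
#'   aggregated NRSE values as the `nrse` attribute.
#' @export
rank_error_proteins <- function(nrse_table, k = 4) {
  df <- as.data.frame(nrse_table)
  agg <- tapply(df$nrse, df$protein, max)
  ord <- order(-as.numeric(agg), names(agg))
  ranked <- names(agg)[ord]
  note <- NULL
  if (k > length(ranked)) {
    note <- sprintf("k = %d exceeds the %d ranked proteins; returning all",
                    k, length(ranked))
    k <- length(ranked)
  }
  structure(ranked[seq_len(k)],
            nrse = as.numeric(agg)[ord][seq_len(k)], note = note)
}

#' Assemble a full concordance report
#'
#' Driver joining the simulation and calibration arms: aligns ensembles with
#' a calibrated secretome, computes per-condition NMAD (both percent and raw
#' fraction), per-protein NRSE, MAX.RSE and the error ranking, and records
#' full provenance (seeds, formula mode, alias map, excluded analytes,
#' steady-state fractions) so the report is reproducible from its inputs.
#'
#' @inheritParams align_model_experiment
#' @param mode,scope passed to [nrse()].
#' @param top_k size of the error ranking. Default 4.
#' @return An object of class `rnm_concordance`: a list with elements
#'   `nmad_pct`, `nmad_fraction`, `nrse`, `max_rse`, `error_ranking`,
#'   `comparison`, `ensembles` (summaries) and `provenance`.
#' @export
concordance_report <- function(ensembles, calibrated,
                               alias_map = default_alias_map(),
                               reference = "control_unloaded",
                               mode = c("difference", "as_printed"),
                               scope = c("condition", "global"),
                               top_k = 4) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  tab <- align_model_experiment(ensembles, calibrated, alias_map, reference)
  er <- nrse(tab, mode = mode, scope = scope)
  ranking <- rank_error_proteins(er, k = top_k)
  structure(list(
    nmad_pct = nmad(tab, percent = TRUE),
    nmad_fraction = nmad(tab, percent = FALSE),
    nrse = as.data.frame(er),
    max_rse = attr(er, "max_rse"),
    error_ranking = as.character(ranking),
    error_ranking_nrse = attr(ranking, "nrse"),
    comparison = as.data.frame(tab),
    ensembles = lapply(unname(ensembles), ensemble_to_list),
    provenance = list(
      mode = mode, scope = scope, reference = reference,
      n_aligned = attr(tab, "n_aligned"),
      unmatched_model = attr(tab, "unmatched_model"),
      unmatched_experiment = attr(tab, "unmatched_experiment"),
      alias_map = alias_map,
      seeds = lapply(ensembles, `[[`, "seed"))),
    class = "rnm_concordance")
}

#' @export
print.rnm_concordance <- function(x, ...) {
  cat("rnm_concordance (mode:", x$provenance$mode, ")\n")
  cat("NMAD (%) per condition:\n")
  print(round(x$nmad_pct, 4))
  cat("worst proteins:", paste(x$error_ranking, collapse = ", "), "\n")
  invisible(x)
}

#' Write a concordance report to JSON and CSV
#'
#' The JSON carries the full report (deterministic field order, no
#' timestamp, so regenerating from the same inputs is byte-identical); the
#' optional CSV holds the aligned comparison pairs with their NRSE.
#'
#' @param report an `rnm_concordance`.
#' @param json_path output JSON path.
#' @param csv_path optional output CSV path.
#' @return `invisible(report)`.
#' @export
write_concordance_report <- function(report, json_path, csv_path = NULL) {
  out <- unclass(report)
  # keep names of per-condition summaries in the JSON
  for (f in c("nmad_pct", "nmad_fraction", "max_rse")) {
    if (!is.null(names(out[[f]]))) out[[f]] <- as.list(out[[f]])
  }
  jsonlite::write_json(out, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(csv_path)) {
    out <- merge(report$comparison, report$nrse,
                 by = c("condition", "protein"))
    utils::write.csv(out[order(out$condition, out$protein), ], csv_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
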