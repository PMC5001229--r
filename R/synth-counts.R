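#' Simulate event-level read-class counts
#'
#' For each event, replicate and condition, reads are assigned
#' multinomially to the three read classes (inclusion-specific,
#' exclusion-specific, shared) with probabilities computed from the true
#' PSI and the event's effective region sizes by [class_probs()] — the
#' same formula the inference likelihood uses, so the simulation is
#' model-consistent by construction. The per-replicate read total is
#' Poisson with mean chosen so that the expected number of
#' isoform-discriminating (inclusion- plus exclusion-specific) reads per
#' condition equals `cfg$depth_per_event`; shared reads ride on top at the
#' model's class odds.
#'
#' @param events list of [splicing_event()]s or a `sim_transcriptome`.
#' @param truth data.frame from [make_truth()]; every event must have a
#'   truth record.
#' @param cfg a [sim_config()].
#' @param eff_table optional precomputed [effective_sizes_table()].
#' @return data.frame with columns `event_id`, `condition`, `replicate`,
#'   `n_inc`, `n_exc`, `n_shared`. Untestable events are omitted.
#' @export
simulate_counts <- function(events, truth, cfg, eff_table = NULL) {
  if (inherits(events, "sim_transcriptome")) events <- events$events
  ids <- vapply(events, `[[`, "", "event_id")
  missing <- setdiff(ids, truth$event_id)
  if (length(missing))
    stop("events without truth record: ", paste(missing, collapse = ", "))
  if (is.null(eff_table))
    eff_table <- effective_sizes_table(events, cfg$read_length)
  rownames(eff_table) <- eff_table$event_id
  rownames(truth) <- truth$event_id

  psi_by_cond <- cbind(truth[ids, "true_psi_control"],
                       truth[ids, "true_psi_treated"])
  colnames(psi_by_cond) <- cfg$conditions

  with_seed(cfg$seed + 1000L, {
    out <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      id <- ids[k]
      eff <- eff_table[id, ]
      if (!isTRUE(eff$testable)) next
      rows <- list()
      for (cond in cfg$conditions) {
        p <- class_probs(psi_by_cond[k, cond], eff)[1, ]
        f_spec <- p[["p_inc"]] + p[["p_exc"]]
        mu <- cfg$depth_per_event / cfg$n_replicates / f_spec
        for (r in seq_len(cfg$n_replicates)) {
          n <- stats::rpois(1L, mu)
          cls <- if (n > 0) stats::rmultinom(1L, n, p)[, 1] else c(0L, 0L, 0L)
          rows[[paste(cond, r)]] <- data.frame(
            event_id = id, condition = cond, replicate = r,
            n_inc = cls[1], n_exc = cls[2], n_shared = cls[3],
            stringsAsFactors = FALSE)
        }
      }
      out[[k]] <- rbind_rows(rows)
    }
  })
  rbind_rows(out)
}
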