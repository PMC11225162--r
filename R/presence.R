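#' Is a pathway step detected in a MAG's gene content?
#'
#' A step is detected when at least one of its variants has ALL required
#' subunits among the MAG's KOs; optional subunits are ignored.
#'
#' @param mag_kos Character vector of KO ids encoded by the MAG.
#' @param step A `mf_step`.
#' @return Logical scalar.
#' @export
detect_step <- function(mag_kos, step) {
  stopifnot(inherits(step, "mf_step"))
  any(vapply(step$variants, function(v) all(v$required %in% mag_kos),
             logical(1)))
}

#' Pathway completeness in a MAG
#'
#' Counts detected key steps and returns the completeness fraction
#' `n_detected / n_key_steps`. The presence decision against the pathway's
#' threshold is made by [call_presence()] in exact integer arithmetic.
#'
#' @param mag_kos Character vector of KO ids encoded by the MAG.
#' @param pathway A `mf_pathway`.
#' @return A list: `n_key_steps`, `n_detected`, `completeness`,
#'   `detected_step_ids` (key steps only).
#' @export
pathway_completeness <- function(mag_kos, pathway) {
  stopifnot(inherits(pathway, "mf_pathway"))
  key_steps <- Filter(function(s) s$key, pathway$steps)
  if (length(key_steps) == 0L) {
    stop(sprintf("pathway '%s' has no key step", pathway$pathway_id),
         call. = FALSE)
  }
  detected <- vapply(key_steps, function(s) detect_step(mag_kos, s),
                     logical(1))
  list(
    n_key_steps = length(key_steps),
    n_detected = sum(detected),
    completeness = sum(detected) / length(key_steps),
    detected_step_ids = vapply(key_steps, `[[`, character(1),
                               "step_id")[detected]
  )
}

# present <=> n_detected / n_key >= threshold, as integer cross-product:
# n_detected * den >= num * n_key. Avoids float artifacts at e.g. 10/11 vs 0.9.
presence_decision <- function(n_detected, n_key, threshold_frac) {
  n_detected * threshold_frac[["den"]] >= threshold_frac[["num"]] * n_key
}

#' Call pathway presence for every MAG and pathway
#'
#' A pathway is considered present in a MAG only when the fraction of its key
#' steps detected from the MAG's KO content reaches the pathway's completeness
#' threshold (default 1.0, i.e. every key step; the methylmalonyl-CoA pathway
#' in the packaged catalog uses 0.9, i.e. at least 10 of its 11 steps, to
#' tolerate MAG incompleteness). The threshold comparison is performed in
#' exact rational arithmetic.
#'
#' @param table A `mf_gene_table` (KO annotations attached).
#' @param catalog A `mf_catalog`.
#' @return A tibble with one row per MAG x pathway: `mag_id`, `pathway_id`,
#'   `n_key_steps`, `n_detected`, `completeness`, `present`,
#'   `detected_step_ids` (list-column), sorted by (pathway_id, mag_id).
#' @export
call_presence <- function(table, catalog) {
  stopifnot(inherits(catalog, "mf_catalog"))
  ko_sets <- mag_ko_sets(table)
  mags <- sort(names(ko_sets))
  rows <- vector("list", length(catalog$pathways) * length(mags))
  k <- 0L
  for (p in catalog$pathways) {
    for (mag in mags) {
      pc <- pathway_completeness(ko_sets[[mag]], p)
      k <- k + 1L
      rows[[k]] <- tibble(
        mag_id = mag, pathway_id = p$pathway_id,
        n_key_steps = pc$n_key_steps, n_detected = pc$n_detected,
        completeness = pc$completeness,
        present = presence_decision(pc$n_detected, pc$n_key_steps,
                                    p$threshold_frac),
        detected_step_ids = list(pc$detected_step_ids)
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$pathway_id, .data$mag_id)
}

#' Write presence calls to TSV
#'
#' @param calls Output of [call_presence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_calls <- function(calls, path) {
  out <- dplyr::mutate(
    calls,
    detected_step_ids = vapply(.data$detected_step_ids, paste, character(1),
                               collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
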