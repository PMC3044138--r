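#' Score site-level T-DMR calls against simulation truth
#'
#' Sensitivity is the fraction of truly differentially methylated sites
#' (|true beta difference| at or above the generator's floor) called
#' significant in the correct direction; the empirical FDR is the
#' fraction of significant calls whose true |difference| is below the
#' floor.
#'
#' @param calls methylation call table from [call_sites()] with contrast
#'   `"between"`.
#' @param truth_sites truth site table from
#'   [generate_infinium_dataset()].
#' @return List with `sensitivity`, `fdr`, `n_true`, `n_called`, and
#'   `direction_ratio_planted` (detected CVS-hypo : MBC-hypo ratio on
#'   the planted panel).
#' @export
evaluate_site_recovery <- function(calls, truth_sites) {
  tr <- truth_sites[match(calls$site_id, truth_sites$site_id), ]
  stopifnot(!anyNA(tr$site_id))
  called <- calls$status %in% c("CVS_hypo", "MBC_hypo")
  correct <- called & calls$status == tr$direction
  sens <- sum(correct & tr$is_tdmr) / sum(tr$is_tdmr)
  fdr <- if (any(called)) sum(called & !tr$is_tdmr) / sum(called) else 0
  planted <- tr$planted
  n_cp <- sum(planted & calls$status == "CVS_hypo" &
                tr$direction == "CVS_hypo")
  n_mp <- sum(planted & calls$status == "MBC_hypo" &
                tr$direction == "MBC_hypo")
  list(sensitivity = sens, fdr = fdr,
       n_true = sum(tr$is_tdmr), n_called = sum(called),
       direction_ratio_planted = n_cp / n_mp)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Score called difference regions against planted regions
#'
#' A planted region counts as recovered when some called region of the
#' matching direction (`CVS_hypo` planted vs `CVS_gt_MBC` called and
#' vice versa, on the same chromosome) overlaps it with interval Jaccard
#' at or above `min_jaccard`; a called region counts as a true call
#' under the mirrored rule.
#'
#' @param called region data.frame from [scan_regions()] (types
#'   `CVS_gt_MBC` / `MBC_gt_CVS`; other types are ignored).
#' @param planted planted region data.frame from the msre truth.
#' @param min_jaccard match threshold, default 0.5.
#' @return List with `sensitivity`, `precision`, `n_planted`,
#'   `n_called`.
#' @export
evaluate_region_recovery <- function(called, planted, min_jaccard = 0.5) {
  type_map <- c(CVS_hypo = "CVS_gt_MBC", MBC_hypo = "MBC_gt_CVS")
  called <- called[called$type %in% type_map, , drop = FALSE]
  match_any <- function(s, e, chrom, pool) {
    if (!nrow(pool)) return(FALSE)
    same <- pool$chrom == chrom
    any(interval_jaccard(s, e, pool$start[same], pool$end[same]) >=
          min_jaccard)
  }
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    match_any(planted$start[i], planted$end[i], planted$chrom[i],
              called[called$type == type_map[planted$type[i]], ,
                     drop = FALSE])
  }, logical(1))
  true_call <- vapply(seq_len(nrow(called)), function(i) {
    want <- names(type_map)[type_map == called$type[i]]
    match_any(called$start[i], called$end[i], called$chrom[i],
              planted[planted$type == want, , drop = FALSE])
  }, logical(1))
  list(sensitivity = mean(recovered),
       precision = if (nrow(called)) mean(true_call) else NA_real_,
       n_planted = nrow(planted), n_called = nrow(called))
}
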