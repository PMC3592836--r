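# Subgroup partition of differential transcripts, five-mode gene-action
# classification, heterosis-mode mapping, and fold-change binning.

SUBGROUP_LEVELS <- c("HTiU", "HTaU", "PPU", "HP1", "HP2", "HPco", "co")

#' Gene-action category to heterosis mode
#'
#' The fixed interpretation map: overdominance (`above_high`),
#' underdominance (`below_low`), dominance toward the high or low parent,
#' and additivity (`mid_parent`).
#'
#' @param category character vector of gene-action categories.
#' @return character vector of heterosis modes.
#' @export
heterosis_mode <- function(category) {
  map <- c(
    below_low = "underdominance",
    low_parent = "dominance_low",
    mid_parent = "additivity",
    high_parent = "dominance_high",
    above_high = "overdominance"
  )
  unname(map[category])
}

#' Partition differential transcripts into the seven Venn subgroups
#'
#' Given the significance pattern over the three comparisons
#' (H vs P1, H vs P2, P1 vs P2), each differential transcript falls in
#' exactly one subgroup: `HTiU`/`HTaU`/`PPU` (unique to one comparison),
#' `HP1` = H-vs-P1 and parental only, `HP2` = H-vs-P2 and parental only,
#' `HPco` = both hybrid comparisons but not parental, `co` = all three.
#' Transcripts significant nowhere are excluded.
#'
#' @param de_calls data frame from [call_de()]; every transcript must
#'   carry all three comparisons.
#' @return data frame `transcript_id`, `subgroup` (factor over the seven
#'   labels), one row per differential transcript.
#' @export
partition_subgroups <- function(de_calls) {
  need <- c("transcript_id", "comparison", "significant")
  if (!all(need %in% names(de_calls))) {
    contract_error("de_calls must have transcript_id, comparison, significant")
  }
  wide <- tapply(
    de_calls$significant,
    list(de_calls$transcript_id, de_calls$comparison),
    any
  )
  if (!all(COMPARISONS %in% colnames(wide)) || anyNA(wide)) {
    contract_error("every transcript needs all three comparisons")
  }
  s1 <- wide[, "H_vs_P1"]
  s2 <- wide[, "H_vs_P2"]
  sp <- wide[, "P1_vs_P2"]
  label <- rep(NA_character_, nrow(wide))
  label[s1 & !s2 & !sp] <- "HTiU"
  label[!s1 & s2 & !sp] <- "HTaU"
  label[!s1 & !s2 & sp] <- "PPU"
  label[s1 & !s2 & sp] <- "HP1"
  label[!s1 & s2 & sp] <- "HP2"
  label[s1 & s2 & !sp] <- "HPco"
  label[s1 & s2 & sp] <- "co"
  keep <- !is.na(label)
  data.frame(
    transcript_id = rownames(wide)[keep],
    subgroup = factor(label[keep], levels = SUBGROUP_LEVELS),
    stringsAsFactors = FALSE
  )
}

#' Classify gene action of a hybrid transcript
#'
#' On pseudo-count-adjusted FPKM, with `m = min(P1, P2)`,
#' `M = max(P1, P2)` and `mid = (P1 + P2)/2`: the transcript is
#' `above_high` (overdominant) when `ln(H/M) > tau`, `below_low`
#' (underdominant) when `ln(m/H) > tau`, and otherwise takes the nearest
#' of the three anchors `m`, `mid`, `M` in absolute log distance
#' (`low_parent`, `mid_parent`, `high_parent`); exact distance ties go to
#' `mid_parent`.  Vectorized.
#'
#' @param fpkm_h,fpkm_p1,fpkm_p2 FPKM values (>= 0).
#' @param tolerance_tau positive log-scale tolerance (default `log(1.5)`).
#' @param pseudo_fpkm stabilizer, same convention as [call_de()].
#' @return data frame `category`, `mode`, `tolerance_used`.
#' @examples
#' classify_gene_action(2.5, 2, 3)$category # "mid_parent"
#' @export
classify_gene_action <- function(fpkm_h, fpkm_p1, fpkm_p2,
                                 tolerance_tau = log(1.5),
                                 pseudo_fpkm = 0.1) {
  if (tolerance_tau <= 0) config_error("tolerance_tau must be > 0")
  if (any(fpkm_h < 0) || any(fpkm_p1 < 0) || any(fpkm_p2 < 0)) {
    contract_error("FPKM values must be >= 0")
  }
  h <- fpkm_h + pseudo_fpkm
  p1 <- fpkm_p1 + pseudo_fpkm
  p2 <- fpkm_p2 + pseudo_fpkm
  m <- pmin(p1, p2)
  mm <- pmax(p1, p2)
  mid <- (p1 + p2) / 2
  cat <- rep(NA_character_, length(h))
  above <- log(h / mm) > tolerance_tau
  below <- !above & log(m / h) > tolerance_tau
  cat[above] <- "above_high"
  cat[below] <- "below_low"
  rest <- !above & !below
  if (any(rest)) {
    dl <- abs(log(h / m))
    dm <- abs(log(h / mid))
    dh <- abs(log(h / mm))
    best <- pmin(dl, dm, dh)
    # ties (dm minimal, or dl == dh == minimum) resolve to mid_parent
    pick <- ifelse(dm <= best, "mid_parent",
      ifelse(dl < dh, "low_parent",
        ifelse(dh < dl, "high_parent", "mid_parent")
      )
    )
    cat[rest] <- pick[rest]
  }
  data.frame(
    category = factor(cat, levels = GENE_ACTION_MODES),
    mode = heterosis_mode(cat),
    tolerance_used = rep(tolerance_tau, length(cat)),
    stringsAsFactors = FALSE
  )
}

#' Bin an ln fold change
#'
#' The study's four fold-change groups for `r = ln(x/hybrid)`:
#' `Up2` (`r < -2`), `Up1` (`-2 <= r < 0`), `None` (`r = 0`),
#' `Down1` (`0 < r <= 2`), `Down2` (`r > 2`).  The printed group
#' definitions leave the boundaries open; exact boundary values are
#' assigned to the adjacent bin nearer zero.
#'
#' @param ln_ratio finite numeric vector.
#' @return factor over `Up1`, `Up2`, `Down1`, `Down2`, `None`.
#' @examples
#' bin_fold_change(c(-2.5, -1, 3)) # Up2, Up1, Down2
#' @export
bin_fold_change <- function(ln_ratio) {
  if (any(!is.finite(ln_ratio))) contract_error("ln_ratio must be finite")
  bin <- ifelse(ln_ratio < -2, "Up2",
    ifelse(ln_ratio < 0, "Up1",
      ifelse(ln_ratio == 0, "None",
        ifelse(ln_ratio <= 2, "Down1", "Down2")
      )
    )
  )
  factor(bin, levels = c("Up1", "Up2", "Down1", "Down2", "None"))
}

#' Gene-action summary table
#'
#' Category-by-subgroup contingency table of hybrid differential
#' transcripts with row/column/grand totals and category percentages of
#' the grand total (one decimal place, half-up).  `PPU` transcripts are
#' not hybrid differential transcripts and must not appear.
#'
#' @param subgroups data frame `transcript_id`, `subgroup` from
#'   [partition_subgroups()] (or equivalent labels).
#' @param action_calls data frame `transcript_id`, `category`.
#' @return list with `counts` (subgroup x category matrix with margins)
#'   and `percent` (named category percentages of the grand total).
#' @export
summarize_actions <- function(subgroups, action_calls) {
  hybrid_levels <- c("HTiU", "HP1", "HPco", "co", "HTaU", "HP2")
  x <- merge(subgroups, action_calls, by = "transcript_id")
  if (any(x$subgroup == "PPU")) {
    contract_error("PPU transcripts are not hybrid DTs; exclude them")
  }
  tab <- table(
    subgroup = factor(as.character(x$subgroup), levels = hybrid_levels),
    category = factor(as.character(x$category), levels = GENE_ACTION_MODES)
  )
  counts <- stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
  grand <- sum(tab)
  pct <- if (grand > 0) {
    round_half_up(100 * colSums(tab) / grand, 1)
  } else {
    stats::setNames(rep(0, length(GENE_ACTION_MODES)), GENE_ACTION_MODES)
  }
  list(counts = counts, percent = pct, grand_total = grand)
}
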