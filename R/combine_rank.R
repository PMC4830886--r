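#' Transfer-corrected benchmark concentration
#'
#' Divides the differentiation BMC50 by the compound's relative Papp, so
#' that rapidly transferred compounds (relative Papp near 1) keep their
#' in vitro potency while slowly transferred ones are down-weighted.
#' Unrounded inputs should be used where available; recomputation from
#' rounded report values can differ in the last printed digit.
#'
#' @param bmc_d50 Benchmark concentration in uM.
#' @param rel_papp Relative Papp (fraction of the reference compound),
#'   must be > 0.
#' @return Corrected BMC in uM.
#' @examples
#' corrected_bmc(4.2, 0.20) # 21
#' @export
corrected_bmc <- function(bmc_d50, rel_papp) {
  if (any(!is.finite(rel_papp)) || any(rel_papp <= 0)) {
    stop("'rel_papp' must be positive", call. = FALSE)
  }
  bmc_d50 / rel_papp
}

#' Potency ranking from potency scores
#'
#' Orders compounds from most to least potent, i.e. by ascending score
#' (lower BMC or corrected BMC = more potent). Ties are flagged and broken
#' by compound id (alphabetical), so the ordering is always deterministic.
#'
#' @param compound_id Compound identifiers.
#' @param value Potency scores (BMC50 or corrected BMC50), uM.
#' @return Character vector of compound ids, most potent first, with
#'   attribute `ties` (ids involved in ties, possibly empty).
#' @examples
#' potency_ranking(c("a", "b", "c"), c(5, 1, 3)) # "b" "c" "a"
#' @export
potency_ranking <- function(compound_id, value) {
  if (length(compound_id) != length(value)) {
    stop("'compound_id' and 'value' lengths differ", call. = FALSE)
  }
  compound_id <- as.character(compound_id)
  dup <- duplicated(value) | duplicated(value, fromLast = TRUE)
  ties <- unique(compound_id[dup])
  if (length(ties)) {
    warning("tied potency values for: ", paste(ties, collapse = ", "),
            "; ties broken by compound id", call. = FALSE)
  }
  ord <- order(value, compound_id)
  structure(compound_id[ord], ties = ties)
}

#' Rank concordance between two orderings
#'
#' Compares two orderings of the same compound set (each given most potent
#' first) by Spearman's rho, Kendall's tau and the number of discordant
#' pairs. Rho and tau are computed on the implied rank vectors.
#'
#' @param order_a,order_b Character vectors listing the same compounds,
#'   most potent first.
#' @return List with `spearman_rho`, `kendall_tau`, `n_discordant`,
#'   `n_pairs`.
#' @examples
#' rank_concordance(c("x", "y", "z"), c("x", "z", "y"))
#' @export
rank_concordance <- function(order_a, order_b) {
  order_a <- as.character(order_a)
  order_b <- as.character(order_b)
  only_a <- setdiff(order_a, order_b)
  only_b <- setdiff(order_b, order_a)
  if (length(only_a) || length(only_b) ||
      length(order_a) != length(order_b)) {
    stop("compound sets differ (only in a: ",
         paste(only_a, collapse = ", "), "; only in b: ",
         paste(only_b, collapse = ", "), ")", call. = FALSE)
  }
  ids <- sort(order_a)
  ra <- match(ids, order_a)
  rb <- match(ids, order_b)
  n <- length(ids)
  pairs <- utils::combn(n, 2)
  disc <- sum(sign(ra[pairs[1, ]] - ra[pairs[2, ]]) !=
                sign(rb[pairs[1, ]] - rb[pairs[2, ]]))
  list(
    spearman_rho = stats::cor(ra, rb, method = "spearman"),
    kendall_tau = stats::cor(ra, rb, method = "kendall"),
    n_discordant = disc,
    n_pairs = ncol(pairs)
  )
}

#' Per-compound summary combining both assays
#'
#' Builds the compound-level table of the combined approach: BMC50,
#' relative Papp, corrected BMC50 and the three potency ranks (rank 1 =
#' most potent).
#'
#' @param compound_id Compound identifiers.
#' @param bmc_d50 Differentiation BMC50 values, uM.
#' @param rel_papp Relative Papp values.
#' @param in_vivo_order Optional external ordering (most potent first) for
#'   the in vivo rank column.
#' @return `data.frame` with columns `compound`, `bmc_d50`, `relative_papp`,
#'   `corrected_bmc_d50`, `in_vitro_rank`, `corrected_rank` and, when the
#'   external ordering is given, `in_vivo_rank`.
#' @export
compound_summary <- function(compound_id, bmc_d50, rel_papp,
                             in_vivo_order = NULL) {
  compound_id <- as.character(compound_id)
  corrected <- corrected_bmc(bmc_d50, rel_papp)
  out <- data.frame(compound = compound_id, bmc_d50 = bmc_d50,
                    relative_papp = rel_papp,
                    corrected_bmc_d50 = corrected,
                    stringsAsFactors = FALSE)
  out$in_vitro_rank <- match(compound_id,
                             potency_ranking(compound_id, bmc_d50))
  out$corrected_rank <- match(compound_id,
                              potency_ranking(compound_id, corrected))
  if (!is.null(in_vivo_order)) {
    out$in_vivo_rank <- match(compound_id, as.character(in_vivo_order))
  }
  out
}

#' Side-by-side ranking table (least to most toxic)
#'
#' Arranges the orderings of the stand-alone differentiation assay, the
#' transfer-corrected combination and the external in vivo assessment as
#' rows from least to most toxic, the conventional presentation for
#' ranking comparisons.
#'
#' @param summaries Output of [compound_summary()] (with in vivo ranks).
#' @return `data.frame` with one row per method and one column per rank
#'   position (`least_toxic` ... `most_toxic`).
#' @export
ranking_table <- function(summaries) {
  stopifnot(is.data.frame(summaries), "in_vivo_rank" %in% names(summaries))
  n <- nrow(summaries)
  row_for <- function(rank_col) {
    summaries$compound[order(summaries[[rank_col]], decreasing = TRUE)]
  }
  out <- rbind(row_for("in_vitro_rank"), row_for("corrected_rank"),
               row_for("in_vivo_rank"))
  out <- data.frame(method = c("differentiation_alone",
                               "differentiation_plus_transfer", "in_vivo"),
                    out, stringsAsFactors = FALSE)
  names(out)[-1] <- c("least_toxic",
                      if (n > 2) paste0("rank_", seq(n - 1, 2)) else NULL,
                      "most_toxic")
  out
}
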