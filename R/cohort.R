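#' RECIST category from the largest tumor diameter
#'
#' Single-lesion RECIST 1.x thresholds: complete response (CR) when the
#' lesion disappears, partial response (PR) at >= 30% shrinkage,
#' progressive disease (PD) at >= 20% growth, stable disease (SD) otherwise.
#'
#' @param d1 baseline largest diameter (mm, > 0).
#' @param d2 follow-up largest diameter (mm, >= 0).
#' @return Character vector of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_recist <- function(d1, d2) {
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n); d2 <- rep_len(d2, n)
  if (any(d1 <= 0 | d2 < 0, na.rm = TRUE))
    stop("diameters must be positive at baseline and non-negative at follow-up")
  change <- (d2 - d1) / d1
  ifelse(d2 == 0, "CR",
  ifelse(change <= -0.30, "PR",
  ifelse(change >= 0.20, "PD", "SD")))
}

#' UICC progressive-disease flag from the bidimensional product
#'
#' Progressive disease under the UICC rule: the product of the largest and
#' perpendicular tumor diameters increased by at least 25% (boundary
#' inclusive).
#'
#' @param l1,p1 baseline largest and perpendicular diameters (mm).
#' @param l2,p2 follow-up diameters (mm).
#' @return Logical vector.
#' @export
classify_uicc_pd <- function(l1, p1, l2, p2) {
  n <- max(length(l1), length(p1), length(l2), length(p2))
  l1 <- rep_len(l1, n); p1 <- rep_len(p1, n)
  l2 <- rep_len(l2, n); p2 <- rep_len(p2, n)
  if (any(c(l1, p1, l2, p2) < 0, na.rm = TRUE)) stop("diameters must be >= 0")
  base <- l1 * p1
  if (any(base == 0, na.rm = TRUE))
    stop("baseline diameter product must be positive")
  (l2 * p2 - base) / base >= 0.25
}

#' Full response assessment for one treatment interval
#'
#' Combines the RECIST diameter rule with the UICC product rule (the latter
#' catching early progression: a UICC-PD flag forces the final category to
#' PD) and dichotomizes into responders (CR or PR, i.e. objective response)
#' versus non-responders (SD or PD).
#'
#' @param measurements data frame with columns `patient_id`,
#'   `largest_t1`, `perp_t1`, `largest_t2`, `perp_t2` (mm).
#' @return The input with `recist`, `uicc_pd`, `category` (final category)
#'   and `responder` appended.
#' @export
assess_response <- function(measurements) {
  req <- c("patient_id", "largest_t1", "perp_t1", "largest_t2", "perp_t2")
  stopifnot(all(req %in% names(measurements)))
  m <- measurements
  m$recist <- classify_recist(m$largest_t1, m$largest_t2)
  m$uicc_pd <- classify_uicc_pd(m$largest_t1, m$perp_t1,
                                m$largest_t2, m$perp_t2)
  m$category <- ifelse(m$uicc_pd, "PD", m$recist)
  m$responder <- m$category %in% c("CR", "PR")
  m
}

#' Compare paired tumor mutational burden by response group
#'
#' Within each response group, compares TMB at two timepoints across
#' patients with both measurements by the paired Wilcoxon signed-rank test
#' and reports group means. Groups with fewer than two complete pairs are
#' reported as not assessable.
#'
#' @param tmb_t1,tmb_t2 named numeric vectors of TMB (names = patient ids).
#' @param responder named logical vector (names = patient ids).
#' @return Data frame with one row per group: `group`, `n_pairs`,
#'   `mean_t1`, `mean_t2`, `p_value`, `assessable`.
#' @export
compare_tmb_by_group <- function(tmb_t1, tmb_t2, responder) {
  ids <- intersect(intersect(names(tmb_t1), names(tmb_t2)), names(responder))
  rows <- lapply(c(TRUE, FALSE), function(g) {
    gid <- ids[responder[ids] == g]
    x1 <- tmb_t1[gid]; x2 <- tmb_t2[gid]
    ok <- !is.na(x1) & !is.na(x2)
    x1 <- x1[ok]; x2 <- x2[ok]
    group <- if (g) "responder" else "non_responder"
    if (length(x1) < 2)
      return(data.frame(group = group, n_pairs = length(x1),
                        mean_t1 = NA_real_, mean_t2 = NA_real_,
                        p_value = NA_real_, assessable = FALSE))
    p <- if (all(x2 - x1 == 0)) 1 else
      suppressWarnings(wilcox.test(x2, x1, paired = TRUE)$p.value)
    data.frame(group = group, n_pairs = length(x1),
               mean_t1 = mean(x1), mean_t2 = mean(x2),
               p_value = p, assessable = TRUE)
  })
  do.call(rbind, rows)
}

#' Gene-wise mutation/response association scan
#'
#' Tests, gene by gene, whether mutated patients respond differently, using
#' the two-sided Fisher exact test on the 2x2 mutated x responder table,
#' with Benjamini-Hochberg correction across the genes tested. Only genes
#' mutated in at least `min_mutated` patients enter the scan; genes with a
#' degenerate table (an empty margin, e.g. all patients mutated) are
#' skipped with a note.
#'
#' @param mutation_matrix logical matrix genes x patients (`TRUE` =
#'   mutated).
#' @param responder named logical vector over the same patients.
#' @param min_mutated minimum number of mutated patients for a gene to be
#'   tested.
#' @return Data frame `gene`, `n_mutated`, `odds_ratio`, `p_value`,
#'   `q_value` (BH), plus a `skipped` attribute naming untestable genes.
#' @export
mutation_response_association <- function(mutation_matrix, responder,
                                          min_mutated = 3L) {
  stopifnot(is.matrix(mutation_matrix), !is.null(rownames(mutation_matrix)))
  patients <- intersect(colnames(mutation_matrix), names(responder))
  if (length(patients) < 2) stop("need at least 2 patients with response labels")
  mm <- mutation_matrix[, patients, drop = FALSE]
  resp <- responder[patients]
  n_mut <- rowSums(mm)
  eligible <- n_mut >= min_mutated
  skipped <- character(0)
  rows <- list()
  for (g in rownames(mm)[eligible]) {
    tab <- table(factor(mm[g, ], levels = c(TRUE, FALSE)),
                 factor(resp, levels = c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      skipped <- c(skipped, g)
      next
    }
    ft <- fisher.test(tab)
    rows[[g]] <- data.frame(gene = g, n_mutated = sum(mm[g, ]),
                            odds_ratio = unname(ft$estimate),
                            p_value = ft$p.value)
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(), n_mutated = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      q_value = numeric())
  } else {
    out <- do.call(rbind, rows)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Trend in mutation frequency across ordered response categories
#'
#' Chi-squared test for trend in proportions (Cochran-Armitage style,
#' [stats::prop.trend.test()]) of mutation carriage across the ordered
#' categories CR > PR > SD > PD.
#'
#' @param mutated named logical vector (patients).
#' @param category named character vector of final response categories.
#' @return `htest` object from [stats::prop.trend.test()].
#' @export
response_trend_test <- function(mutated, category) {
  lev <- c("CR", "PR", "SD", "PD")
  ids <- intersect(names(mutated), names(category))
  cat_f <- factor(category[ids], levels = lev)
  x <- tapply(mutated[ids], cat_f, sum, default = 0L)
  n <- tapply(rep(1L, length(ids)), cat_f, sum, default = 0L)
  keep <- n > 0
  prop.trend.test(x[keep], n[keep])
}
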