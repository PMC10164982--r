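#' Aggregate method-wise stability rankings (RefFinder-style)
#'
#' Within each of the four methods the candidates are ranked ascending by
#' their stability statistic (lower = more stable; ties get the average
#' rank). The comprehensive "stability value" of a candidate is the
#' geometric mean of its four ranks, so it is invariant to any strictly
#' increasing transform of a method's statistic. geNorm contributes its
#' iterative-exclusion rank (final pair tied at 1.5) rather than a rank of
#' raw M values.
#'
#' @param report a [stability_report()] data.frame (columns `gene`,
#'   `genorm_rank`, `normfinder_rho`, `bestkeeper_sd`, `deltact_stability`).
#' @return data.frame of class `aggregated_ranking`, sorted ascending by
#'   `stability_value`: `gene`, the four per-method ranks, and
#'   `stability_value`.
#' @export
#' @examples
#' rep <- data.frame(gene = c("A", "B"), genorm_rank = c(1.5, 1.5),
#'                   normfinder_rho = c(0.1, 0.4),
#'                   bestkeeper_sd = c(0.2, 0.5),
#'                   deltact_stability = c(0.3, 0.6))
#' aggregate_ranks(rep)$stability_value
aggregate_ranks <- function(report) {
  need <- c("gene", "genorm_rank", "normfinder_rho", "bestkeeper_sd",
            "deltact_stability")
  missing_cols <- setdiff(need, names(report))
  if (length(missing_cols) > 0) {
    stop("stability report lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(report) < 2) stop("need at least 2 candidates to rank")
  bad <- report$gene[!stats::complete.cases(report[, need])]
  if (length(bad) > 0) {
    stop("missing statistic for candidate(s): ", paste(bad, collapse = ", "))
  }
  ranks <- data.frame(
    gene = report$gene,
    genorm = report$genorm_rank,
    normfinder = rank(report$normfinder_rho, ties.method = "average"),
    bestkeeper = rank(report$bestkeeper_sd, ties.method = "average"),
    deltact = rank(report$deltact_stability, ties.method = "average"),
    stringsAsFactors = FALSE
  )
  ranks$stability_value <- apply(
    ranks[, c("genorm", "normfinder", "bestkeeper", "deltact")], 1, geom_mean
  )
  ranks <- ranks[order(ranks$stability_value, ranks$gene), , drop = FALSE]
  rownames(ranks) <- NULL
  class(ranks) <- c("aggregated_ranking", "data.frame")
  ranks
}

#' Append geometric-mean pseudo-genes for candidate combinations
#'
#' Every k-subset of genes becomes a pseudo-gene whose Ct in each sample is
#' the geometric mean of the member Ct values, named by joining the member
#' names with `+`. The extended matrix (originals first, then combinations)
#' can be fed back through the stability methods so single candidates and
#' combinations compete in one ranking.
#'
#' @param ct numeric gene x sample Ct matrix.
#' @param k combination size (default 2; must be >= 2 and <= number of
#'   genes).
#' @param genes optional subset of genes to combine (default all).
#' @return extended Ct matrix with `choose(length(genes), k)` pseudo-gene
#'   rows appended.
#' @export
make_combinations <- function(ct, k = 2, genes = rownames(ct)) {
  ct <- as_ct_values(ct)
  stopifnot_matrix(ct)
  if (k < 2) stop("combination size k must be at least 2")
  if (k > length(genes)) stop("k exceeds the number of genes")
  combos <- combn(genes, k)
  pseudo <- apply(combos, 2, function(members) {
    apply(ct[members, , drop = FALSE], 2, geom_mean)
  })
  pseudo <- t(pseudo)
  rownames(pseudo) <- apply(combos, 2, paste, collapse = "+")
  rbind(ct, pseudo)
}

#' Coefficient of variation of candidate normalizers over control samples
#'
#' Computes, per candidate, `CV = 100 * SD(dCt) / |mean(dCt)|` over the
#' control samples. Two readings of "Ct normalized to the endogenous
#' control" are supported: `"self-vs-calibrator"` (default) normalizes the
#' candidate's Ct to the pooled inter-run calibrator of the sample's run,
#' and `"targets-vs-candidate"` pools the dCt of a designated target set
#' normalized to the candidate. Candidates whose |mean dCt| falls below
#' `eps` are flagged: their CV blows up by construction (the paper-style
#' CV > 200% exclusions), and the flag keeps that interpretable.
#'
#' @param ct gene x sample Ct matrix still containing the calibrator
#'   columns (for the default mode).
#' @param meta sample metadata (`sample_id`, `group`, `run`,
#'   `is_calibrator`).
#' @param candidates candidate (pseudo-)gene names; default all rows.
#' @param mode `"self-vs-calibrator"` or `"targets-vs-candidate"`.
#' @param targets target gene names (required for the second mode).
#' @param eps |mean dCt| below which a candidate is flagged
#'   unstable-by-construction (cycles).
#' @return data.frame: `candidate`, `cv_percent`, `mean_dct`, `sd_dct`,
#'   `near_zero_mean`.
#' @export
cv_of_candidates <- function(ct, meta, candidates = rownames(ct),
                             mode = c("self-vs-calibrator",
                                      "targets-vs-candidate"),
                             targets = NULL, eps = 0.05) {
  mode <- match.arg(mode)
  ct <- as_ct_values(ct)
  meta <- meta[match(colnames(ct), meta$sample_id), , drop = FALSE]
  ctrl <- meta$sample_id[!meta$is_calibrator &
                           !is.na(meta$group) & meta$group == "control"]
  if (length(ctrl) < 3) {
    stop("need at least 3 control samples to compute a CV (got ",
         length(ctrl), ")")
  }
  dct_of <- function(cand) {
    if (mode == "self-vs-calibrator") {
      cal <- vapply(ctrl, function(s) {
        r <- meta$run[meta$sample_id == s]
        cal_s <- meta$sample_id[meta$run == r & meta$is_calibrator][1]
        if (is.na(cal_s)) stop("run '", r, "' has no calibrator sample")
        ct[cand, cal_s]
      }, numeric(1))
      ct[cand, ctrl] - cal
    } else {
      if (is.null(targets)) {
        stop("mode 'targets-vs-candidate' requires 'targets'")
      }
      as.vector(sweep(ct[targets, ctrl, drop = FALSE], 2, ct[cand, ctrl], "-"))
    }
  }
  rows <- lapply(candidates, function(cand) {
    d <- dct_of(cand)
    m <- mean(d)
    s <- sd(d)
    data.frame(candidate = cand,
               cv_percent = 100 * s / abs(m),
               mean_dct = m, sd_dct = s,
               near_zero_mean = abs(m) < eps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the endogenous control from ranking and CV evidence
#'
#' Candidates with `CV > cv_max` (default 200%) are excluded as too
#' variable; among the survivors the candidate with the lowest
#' comprehensive stability value wins, with lower CV breaking ties. A
#' shortlist of candidates with `stability_value < stability_max`
#' (default 5) is also reported, mirroring the screening rule used for
#' pre-spotted control panels.
#'
#' @param ranking an [aggregate_ranks()] result.
#' @param cvs a [cv_of_candidates()] result covering the same candidates.
#' @param cv_max CV exclusion threshold in percent.
#' @param stability_max shortlist threshold on the stability value.
#' @return list of class `candidate_set`: `selected` (candidate name),
#'   `verdicts` (data.frame with ranks, stability value, CV, verdict and
#'   reason), `shortlist`.
#' @export
select_endogenous_control <- function(ranking, cvs, cv_max = 200,
                                      stability_max = 5) {
  tab <- merge(as.data.frame(ranking), cvs, by.x = "gene",
               by.y = "candidate", all = FALSE)
  if (nrow(tab) < nrow(ranking) || nrow(tab) < nrow(cvs)) {
    stop("ranking and CV tables must cover the same candidates")
  }
  excluded <- tab$cv_percent > cv_max
  tab$verdict <- ifelse(excluded, "excluded", "candidate")
  tab$reason <- ifelse(
    excluded, sprintf("CV %.0f%% > %.0f%%", tab$cv_percent, cv_max), ""
  )
  if (all(excluded)) {
    stop("all candidates excluded by CV > ", cv_max,
         "%; review the cv_max threshold")
  }
  surv <- tab[!excluded, , drop = FALSE]
  surv <- surv[order(surv$stability_value, surv$cv_percent, surv$gene), ,
               drop = FALSE]
  selected <- surv$gene[1]
  tab$verdict[tab$gene == selected] <- "selected"
  tab$reason[tab$gene == selected] <- "lowest stability value among survivors"
  tab <- tab[order(tab$stability_value, tab$cv_percent, tab$gene), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(selected = selected,
         verdicts = tab,
         shortlist = tab$gene[tab$stability_value < stability_max &
                                tab$verdict != "excluded"]),
    class = "candidate_set"
  )
}
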