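# Scoring detections against ground truth: one-to-one mark/nodule
# matching, sensitivity and FP per case, FROC curves, and the JAFROC
# figure of merit with a jackknife resampler.

#' Flatten ground truth into a nodule table
#'
#' Accepts a single `ground_truth` object (from the phantom module), a
#' list of them, or an already-flat data frame with columns `case_id`,
#' `x_mm`, `y_mm`, `z_mm`, `diameter_mm`.
#'
#' @param truth ground truth in any of the accepted forms.
#' @param spacing_mm spacing used to convert voxel centers to mm when
#'   needed.
#' @return data frame with one row per true nodule.
#' @export
truth_table <- function(truth, spacing_mm = c(1, 1, 1)) {
  if (is.data.frame(truth)) return(truth)
  if (inherits(truth, "ground_truth")) truth <- list(truth)
  ids <- vapply(truth, function(g) g$case_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate case ids in ground truth: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  do.call(rbind, lapply(truth, function(g) {
    if (nrow(g$nodules) == 0L)
      return(data.frame(case_id = character(0), x_mm = numeric(0),
                        y_mm = numeric(0), z_mm = numeric(0),
                        diameter_mm = numeric(0), kind = character(0)))
    mm <- voxel_to_mm(as.matrix(g$nodules[, c("i", "j", "k")]), spacing_mm)
    data.frame(case_id = g$case_id, x_mm = mm[, 1], y_mm = mm[, 2],
               z_mm = mm[, 3], diameter_mm = g$nodules$diameter_mm,
               kind = g$nodules$kind, stringsAsFactors = FALSE)
  }))
}

#' Match detection marks to true nodules
#'
#' A mark hits a nodule when its position lies within
#' `nodule radius + hit_margin_mm` of the nodule centre.  Assignment is
#' one-to-one and greedy: marks are visited by descending probability,
#' ties broken by ascending distance, and each mark claims its nearest
#' still-unclaimed nodule in range.  Unmatched marks are false positives;
#' unmatched nodules are misses.
#'
#' @param marks data frame of detections: `case_id, x_mm, y_mm, z_mm,
#'   probability`.
#' @param truth nodule table (see [truth_table]).
#' @param hit_margin_mm matching slack in mm (default 1, one voxel at
#'   1 mm resolution).
#' @param case_ids full case universe including control cases with
#'   neither marks nor nodules; defaults to the cases present in `marks`
#'   and `truth`.
#' @return A `cad_matching` object: the mark table with `matched_nodule`
#'   and `is_tp`, the nodule table with `hit`, the case universe and the
#'   margin used.
#' @export
match_marks <- function(marks, truth, hit_margin_mm = 1, case_ids = NULL) {
  truth <- truth_table(truth)
  if (is.null(case_ids))
    case_ids <- sort(unique(c(marks$case_id, truth$case_id)))
  if (anyDuplicated(case_ids)) stop("duplicate case ids")
  marks <- as.data.frame(marks)
  if (is.null(marks$probability)) marks$probability <- rep(1, nrow(marks))
  truth$nodule_id <- seq_len(nrow(truth))
  truth$hit <- rep(FALSE, nrow(truth))
  marks$matched_nodule <- rep(NA_integer_, nrow(marks))
  marks$is_tp <- rep(FALSE, nrow(marks))
  if (nrow(marks)) {
    for (cid in unique(marks$case_id)) {
      mi <- which(marks$case_id == cid)
      ti <- which(truth$case_id == cid)
      if (!length(ti)) next
      tc <- as.matrix(truth[ti, c("x_mm", "y_mm", "z_mm")])
      rad <- truth$diameter_mm[ti] / 2 + hit_margin_mm
      # distances mark x nodule
      dmat <- sapply(seq_along(ti), function(s)
        sqrt((marks$x_mm[mi] - tc[s, 1])^2 + (marks$y_mm[mi] - tc[s, 2])^2 +
             (marks$z_mm[mi] - tc[s, 3])^2))
      dmat <- matrix(dmat, nrow = length(mi))
      near <- apply(dmat, 1, min)
      ord <- order(-marks$probability[mi], near)
      claimed <- rep(FALSE, length(ti))
      for (m in ord) {
        ok <- which(!claimed & dmat[m, ] <= rad)
        if (!length(ok)) next
        pick <- ok[which.min(dmat[m, ok])]
        claimed[pick] <- TRUE
        marks$matched_nodule[mi[m]] <- truth$nodule_id[ti[pick]]
        marks$is_tp[mi[m]] <- TRUE
      }
      truth$hit[ti] <- claimed
    }
  }
  structure(list(marks = marks, nodules = truth, case_ids = case_ids,
                 hit_margin_mm = hit_margin_mm),
            class = "cad_matching")
}

#' Sensitivity and false positives per case
#'
#' Sensitivity is the fraction of true nodules hit (optionally restricted
#' to nodules with diameter strictly greater than `size_floor_mm`); FP per
#' case is the number of unmatched marks divided by the number of cases in
#' the universe, controls included.
#'
#' @param matching a `cad_matching` from [match_marks].
#' @param size_floor_mm nodules with diameter `<= size_floor_mm` are
#'   excluded from the sensitivity (default `NULL`: all nodules count).
#' @return list with `sensitivity`, `fp_per_case`, and the underlying
#'   counts.
#' @export
sensitivity_fp <- function(matching, size_floor_mm = NULL) {
  stopifnot(inherits(matching, "cad_matching"))
  nod <- matching$nodules
  if (nrow(nod) == 0L) stop("empty ground truth: sensitivity is undefined")
  if (!is.null(size_floor_mm))
    nod <- nod[nod$diameter_mm > size_floor_mm, , drop = FALSE]
  if (nrow(nod) == 0L)
    stop("no nodules above the size floor of ", size_floor_mm, " mm")
  n_fp <- sum(!matching$marks$is_tp)
  n_cases <- length(matching$case_ids)
  list(sensitivity = sum(nod$hit) / nrow(nod),
       fp_per_case = n_fp / n_cases,
       n_hit = sum(nod$hit), n_nodules = nrow(nod),
       n_fp = n_fp, n_cases = n_cases)
}

#' FROC curve
#'
#' Sweeps a probability cutoff over the sorted unique mark probabilities
#' (plus 0) and recomputes sensitivity and FP per case at each operating
#' point.  Both are non-increasing as the cutoff rises.
#'
#' @inheritParams match_marks
#' @param thresholds explicit cutoffs; default the unique mark
#'   probabilities.
#' @param size_floor_mm passed to [sensitivity_fp].
#' @return data frame `threshold, sensitivity, fp_per_case`.
#' @export
froc_curve <- function(marks, truth, thresholds = NULL, hit_margin_mm = 1,
                       case_ids = NULL, size_floor_mm = NULL) {
  truth <- truth_table(truth)
  if (is.null(case_ids))
    case_ids <- sort(unique(c(marks$case_id, truth$case_id)))
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, marks$probability)))
  rows <- lapply(thresholds, function(ct) {
    sub <- marks[marks$probability >= ct, , drop = FALSE]
    m <- match_marks(sub, truth, hit_margin_mm, case_ids)
    sf <- sensitivity_fp(m, size_floor_mm)
    data.frame(threshold = ct, sensitivity = sf$sensitivity,
               fp_per_case = sf$fp_per_case)
  })
  do.call(rbind, rows)
}

#' JAFROC figure of merit
#'
#' The probability that a lesion is rated higher than a non-lesion mark:
#' the mean over all (lesion, non-lesion) rating pairs of the indicator
#' `rating_lesion > rating_nonlesion`, with ties scoring 0.5.  Unmarked
#' lesions enter at `-Inf`.  The value is invariant under any strictly
#' monotone transform of the ratings.  Computed via the rank-sum identity
#' (Mann-Whitney U); the brute-force pairwise definition is the test
#' oracle.
#'
#' @param lesion_ratings rating per true lesion (`-Inf` when unmarked).
#' @param nonlesion_ratings one rating per normal case: the case's
#'   highest-rated false-positive mark (`-Inf` when the case has no
#'   marks).
#' @return FOM in `[0, 1]`.
#' @export
jafroc_fom <- function(lesion_ratings, nonlesion_ratings) {
  nl <- length(lesion_ratings)
  nn <- length(nonlesion_ratings)
  if (nl == 0L || nn == 0L)
    stop("FOM undefined: need at least one lesion and one normal-case rating")
  r <- rank(c(lesion_ratings, nonlesion_ratings))
  u <- sum(r[seq_len(nl)]) - nl * (nl + 1) / 2
  u / (nl * nn)
}

#' Build JAFROC ratings from detections and truth
#'
#' Matches all marks (no cutoff) to nodules; each lesion's rating is the
#' probability of the mark it matched (`-Inf` if unmarked).  Non-lesion
#' ratings are, under the default `"normal_only"` variant, the highest FP
#' mark probability per case without lesions; normal cases carrying no
#' marks contribute no rating, so deleting such a case never moves the
#' FOM.  The `"all_cases"` variant uses the highest FP mark on every
#' marked case.
#'
#' @inheritParams match_marks
#' @param fom_variant `"normal_only"` or `"all_cases"`.
#' @return list with `lesion_ratings`, `nonlesion_ratings`, and `fom`.
#' @export
fom_from_detections <- function(marks, truth, case_ids = NULL,
                                hit_margin_mm = 1,
                                fom_variant = c("normal_only", "all_cases")) {
  fom_variant <- match.arg(fom_variant)
  truth <- truth_table(truth)
  if (is.null(case_ids))
    case_ids <- sort(unique(c(marks$case_id, truth$case_id)))
  m <- match_marks(marks, truth, hit_margin_mm, case_ids)
  les <- rep(-Inf, nrow(m$nodules))
  hitrows <- m$marks[m$marks$is_tp, , drop = FALSE]
  les[match(hitrows$matched_nodule, m$nodules$nodule_id)] <-
    hitrows$probability
  fp <- m$marks[!m$marks$is_tp, , drop = FALSE]
  nl_cases <- if (fom_variant == "normal_only")
    setdiff(case_ids, unique(truth$case_id)) else case_ids
  nl_cases <- intersect(nl_cases, unique(fp$case_id))
  non <- vapply(nl_cases, function(cid)
    max(fp$probability[fp$case_id == cid]), numeric(1))
  list(lesion_ratings = les, nonlesion_ratings = unname(non),
       fom = jafroc_fom(les, unname(non)))
}

#' Jackknife resampling of the figure of merit
#'
#' Leave-one-case-out recomputation of the FOM, pseudovalues
#' `n * FOM - (n - 1) * FOM_(-i)`, their mean and standard error.
#' Replicates where the FOM is undefined after deletion (e.g. removing
#' the only normal case) are flagged and excluded from the pseudovalue
#' summary.
#'
#' @inheritParams fom_from_detections
#' @return list with `fom`, `pseudovalues`, `mean`, `se`, `loo` (per-case
#'   leave-one-out FOMs) and `degenerate` (case ids with undefined
#'   replicates).
#' @export
jackknife_fom <- function(marks, truth, case_ids = NULL, hit_margin_mm = 1,
                          fom_variant = "normal_only") {
  truth <- truth_table(truth)
  if (is.null(case_ids))
    case_ids <- sort(unique(c(marks$case_id, truth$case_id)))
  n <- length(case_ids)
  if (n < 2L) stop("jackknife needs at least 2 cases")
  full <- fom_from_detections(marks, truth, case_ids, hit_margin_mm,
                              fom_variant)$fom
  loo <- vapply(case_ids, function(cid) {
    keep <- setdiff(case_ids, cid)
    tryCatch(fom_from_detections(marks[marks$case_id != cid, , drop = FALSE],
                                 truth[truth$case_id != cid, , drop = FALSE],
                                 keep, hit_margin_mm, fom_variant)$fom,
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(loo)
  pv <- n * full - (n - 1) * loo[ok]
  list(fom = full, loo = loo, pseudovalues = pv, mean = mean(pv),
       se = sd(pv) / sqrt(length(pv)),
       degenerate = case_ids[!ok])
}
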