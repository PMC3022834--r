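# Eligibility, concurrent CD4/VL pairing and three-point slope endpoints.

#' Pair CD4 tests with concurrent viral-load tests
#'
#' One pair per CD4 test, matched to the nearest-in-time VL test within 28
#' days; each VL test anchors at most one pair.  Same-day pairs are matched
#' first; remaining CD4 tests are matched greedily in chronological order,
#' ties at equal distance resolved towards the earlier VL test.  CD4 tests
#' with no VL test within the window emit no pair.
#'
#' @param labs long-format lab table (patient_id, date, analyte, value) with
#'   analytes \code{"CD4"} and \code{"VL"}.
#' @param patients patients table supplying \code{cart_start} (a
#'   \code{\link{cohort_tables}} object may be given instead of \code{labs},
#'   in which case \code{patients} is taken from it).
#' @param window_days maximum days between the two tests (default 28).
#' @return data.frame with columns patient_id, t_days (CD4 test day since
#'   cART start), cd4, log10_vl, days_apart.
#' @export
pair_concurrent <- function(labs, patients = NULL, window_days = 28) {
  if (inherits(labs, "cd4_cohort")) {
    patients <- labs$patients
    labs <- labs$labs
  }
  if (is.null(patients))
    stop("pair_concurrent: patients table required for cART start dates",
         call. = FALSE)
  empty <- data.frame(patient_id = character(), t_days = numeric(),
                      cd4 = numeric(), log10_vl = numeric(),
                      days_apart = numeric(), stringsAsFactors = FALSE)
  if (!nrow(labs)) return(empty)
  start <- patients$cart_start[match(labs$patient_id, patients$patient_id)]
  day <- as.numeric(labs$date - start)
  cd4 <- labs$analyte == "CD4"
  vl <- labs$analyte == "VL"
  idx_c <- split(which(cd4), labs$patient_id[cd4])
  idx_v <- split(which(vl), labs$patient_id[vl])
  out <- vector("list", 0L)
  for (id in names(idx_c)) {
    sel_c <- idx_c[[id]]
    sel_v <- idx_v[[id]]
    if (is.null(sel_v)) next
    cdays <- day[sel_c]; cvals <- labs$value[sel_c]
    ord <- order(cdays); cdays <- cdays[ord]; cvals <- cvals[ord]
    vdays <- day[sel_v]; vvals <- labs$value[sel_v]
    ordv <- order(vdays); vdays <- vdays[ordv]; vvals <- vvals[ordv]
    used <- rep(FALSE, length(vdays))
    match_v <- rep(NA_integer_, length(cdays))
    # same-day matches first
    for (k in seq_along(cdays)) {
      j <- which(!used & vdays == cdays[k])
      if (length(j)) { match_v[k] <- j[1]; used[j[1]] <- TRUE }
    }
    # then nearest available within the window, in time order
    for (k in which(is.na(match_v))) {
      d <- abs(vdays - cdays[k])
      d[used | d > window_days] <- Inf
      if (all(is.infinite(d))) next
      j <- which(d == min(d))[1]        # tie: earlier VL (vdays sorted)
      match_v[k] <- j; used[j] <- TRUE
    }
    keep <- !is.na(match_v)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = id,
        t_days = cdays[keep],
        cd4 = cvals[keep],
        log10_vl = log10(vvals[match_v[keep]]),
        days_apart = abs(vdays[match_v[keep]] - cdays[keep]),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Patients eligible for the slope analysis
#'
#' Retains patients whose initial regimen comprised three or more drugs and
#' who have three or more concurrent CD4/VL pairs beyond 183 days after
#' cART initiation.
#'
#' @param cohort a \code{\link{cohort_tables}} object.
#' @param pairs output of \code{\link{pair_concurrent}}.
#' @param min_pairs minimum number of post-183-day pairs (default 3).
#' @return character vector of patient ids.
#' @export
eligible_patients <- function(cohort, pairs, min_pairs = 3) {
  tr <- cohort$treatments
  start <- cohort$patients$cart_start[match(tr$patient_id,
                                            cohort$patients$patient_id)]
  ord <- order(tr$patient_id, as.numeric(tr$start - start))
  tr <- tr[ord, , drop = FALSE]
  first <- !duplicated(tr$patient_id)
  ndrugs <- lengths(strsplit(tr$classes[first], ",", fixed = TRUE))
  triple <- tr$patient_id[first][ndrugs >= 3]
  late <- pairs[pairs$t_days > PHASE_BOUNDARY_DAYS, , drop = FALSE]
  counts <- table(late$patient_id)
  enough <- names(counts)[counts >= min_pairs]
  sort(intersect(triple, enough))
}

#' Three-point CD4 slope
#'
#' Ordinary-least-squares slope of CD4 count on time over exactly three
#' measurements, with time converted from days to years (days / 365.25).
#'
#' @param t_days three strictly increasing days since cART initiation.
#' @param cd4 three CD4 counts, cells/uL.
#' @return slope in cells/uL per year.
#' @export
compute_slope <- function(t_days, cd4) {
  if (length(t_days) != 3L || length(cd4) != 3L)
    stop("compute_slope: exactly three points required", call. = FALSE)
  if (any(diff(t_days) <= 0))
    stop("compute_slope: times must be strictly increasing (no duplicates)",
         call. = FALSE)
  t <- t_days / DAYS_PER_YEAR
  tc <- t - mean(t)
  sum(tc * (cd4 - mean(cd4))) / sum(tc^2)
}

#' Build slope endpoints with time-updated covariates
#'
#' One endpoint per interior pair (a pair with a neighbouring pair strictly
#' before and after it within the same patient).  The slope is the
#' three-point OLS slope over the triplet's CD4 values; covariates are
#' evaluated at the endpoint time T: current age; disease stage (TB-ADI if
#' any TB event on or before T, else non-TB ADI if any such event, else the
#' reference category); haemoglobin by last observation carried forward
#' (patients never tested receive the cohort median at initiation);
#' concurrent CD4 and log10 VL from the pair at T; analysis period from
#' t_days; and patient-level regimen/hepatitis indicators.
#'
#' All endpoints are returned, including those at or before 183 days (used
#' by \code{\link{phase_slope_summary}}); regression modelling restricts to
#' \code{t_days > 183}.
#'
#' @param cohort a \code{\link{cohort_tables}} object.
#' @param pairs output of \code{\link{pair_concurrent}}, already filtered to
#'   eligible patients if eligibility is to apply.
#' @return data.frame, one row per endpoint.
#' @export
build_endpoints <- function(cohort, pairs) {
  pts <- cohort$patients
  empty <- data.frame(patient_id = character(), t_days = numeric(),
                      slope = numeric(), female = integer(),
                      age_decades = numeric(), stage = character(),
                      haemoglobin = numeric(), cd4_per100 = numeric(),
                      log10_vl = numeric(), hepatitis = integer(),
                      period = character(), nnrti = integer(),
                      boosted_pi = integer(), abacavir = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  ord <- order(pairs$patient_id, pairs$t_days)
  pairs <- pairs[ord, , drop = FALSE]

  # per-patient interior rows
  n_by <- table(pairs$patient_id)[unique(pairs$patient_id)]
  idx_first <- cumsum(c(1, utils::head(as.numeric(n_by), -1)))
  interior <- unlist(lapply(seq_along(n_by), function(i) {
    m <- as.numeric(n_by[i])
    if (m < 3) return(integer(0))
    idx_first[i] + seq(1, m - 2)
  }))
  if (!length(interior)) return(empty)

  slope <- vapply(interior, function(k) {
    compute_slope(pairs$t_days[(k - 1):(k + 1)], pairs$cd4[(k - 1):(k + 1)])
  }, numeric(1))

  ep <- pairs[interior, , drop = FALSE]
  pi <- match(ep$patient_id, pts$patient_id)
  date_T <- pts$cart_start[pi] + ep$t_days

  # stage at T from dated events
  ev <- cohort$events
  stage <- rep("REF", nrow(ep))
  if (nrow(ev)) {
    ev_day <- as.numeric(ev$date -
      pts$cart_start[match(ev$patient_id, pts$patient_id)])
    key_ep <- ep$patient_id
    for (type in c("NONTB_ADI", "TB_ADI")) {   # TB last: takes precedence
      sel <- ev$event == type
      if (!any(sel)) next
      first_day <- tapply(ev_day[sel], ev$patient_id[sel], min)
      d <- first_day[key_ep]
      hit <- !is.na(d) & d <= ep$t_days
      stage[hit] <- type
    }
  }

  # haemoglobin LOCF; never-tested patients get the cohort baseline median
  hb <- rep(NA_real_, nrow(ep))
  hb_labs <- cohort$labs[cohort$labs$analyte == "HB", , drop = FALSE]
  if (nrow(hb_labs)) {
    hb_day <- as.numeric(hb_labs$date -
      pts$cart_start[match(hb_labs$patient_id, pts$patient_id)])
    o <- order(hb_labs$patient_id, hb_day)
    hb_labs <- hb_labs[o, , drop = FALSE]; hb_day <- hb_day[o]
    baseline_hb <- tapply(hb_labs$value, hb_labs$patient_id, function(v) v[1])
    cohort_median_hb <- stats::median(baseline_hb)
    hb_idx <- split(seq_len(nrow(hb_labs)), hb_labs$patient_id)
    ep_idx <- split(seq_len(nrow(ep)), ep$patient_id)
    for (id in names(ep_idx)) {
      rows <- ep_idx[[id]]
      h <- hb_idx[[id]]
      if (is.null(h)) { hb[rows] <- cohort_median_hb; next }
      pos <- findInterval(ep$t_days[rows], hb_day[h])
      val <- ifelse(pos >= 1, hb_labs$value[h][pmax(pos, 1)],
                    cohort_median_hb)
      hb[rows] <- val
    }
  }

  data.frame(patient_id = ep$patient_id,
             t_days = ep$t_days,
             slope = slope,
             female = as.integer(pts$sex[pi] == "F"),
             age_decades = as.numeric(date_T - pts$birth_date[pi]) /
               DAYS_PER_YEAR / 10,
             stage = stage,
             haemoglobin = hb,
             cd4_per100 = ep$cd4 / 100,
             log10_vl = ep$log10_vl,
             hepatitis = as.integer(pts$hepatitis_bc[pi]),
             period = as.character(period_of_days(ep$t_days)),
             nnrti = as.integer(pts$regimen_nnrti[pi]),
             boosted_pi = as.integer(pts$regimen_boosted_pi[pi]),
             abacavir = as.integer(pts$abacavir[pi]),
             stringsAsFactors = FALSE)
}

#' Two-phase summary of CD4 slopes
#'
#' Mean slope among endpoints at or before \code{boundary_days} versus
#' afterwards, with a two-sided Welch two-sample test.
#'
#' @param endpoints endpoint table from \code{\link{build_endpoints}},
#'   computed over all follow-up.
#' @param boundary_days phase boundary (default 183 days).
#' @return list with mean_slope_early, mean_slope_late, n_early, n_late,
#'   p_value and an \code{empty_phase} flag.
#' @export
phase_slope_summary <- function(endpoints, boundary_days = PHASE_BOUNDARY_DAYS) {
  early <- endpoints$slope[endpoints$t_days <= boundary_days]
  late <- endpoints$slope[endpoints$t_days > boundary_days]
  empty <- length(early) == 0 || length(late) == 0
  p <- NA_real_
  if (!empty && (stats::sd(early) > 0 || stats::sd(late) > 0))
    p <- stats::t.test(early, late, alternative = "two.sided")$p.value
  else if (!empty)
    p <- 1
  list(mean_slope_early = if (length(early)) mean(early) else NA_real_,
       mean_slope_late = if (length(late)) mean(late) else NA_real_,
       n_early = length(early), n_late = length(late),
       p_value = p, empty_phase = empty)
}

#' Sensitivity-analysis subsets of the endpoint table
#'
#' \code{"INITIAL_REGIMEN"} keeps endpoints dated strictly before any
#' drug-class change and before any off-treatment gap longer than 30 days;
#' \code{"INITIAL_NNRTI"} additionally requires an NNRTI-based initial
#' regimen; \code{"MIN4"} keeps patients contributing at least four
#' endpoints in the given table.
#'
#' @param endpoints endpoint table.
#' @param cohort the \code{\link{cohort_tables}} the endpoints came from.
#' @param rule one of \code{"INITIAL_REGIMEN"}, \code{"INITIAL_NNRTI"},
#'   \code{"MIN4"}.
#' @param max_gap_days maximal tolerated off-treatment gap (default 30).
#' @return filtered endpoint table.
#' @export
sensitivity_subset <- function(endpoints, cohort,
                               rule = c("INITIAL_REGIMEN", "INITIAL_NNRTI",
                                        "MIN4"),
                               max_gap_days = 30) {
  if (length(rule) != 1L || !rule %in% c("INITIAL_REGIMEN", "INITIAL_NNRTI",
                                         "MIN4"))
    stop("sensitivity_subset: unknown rule '",
         paste(rule, collapse = ","), "'", call. = FALSE)
  if (rule == "MIN4") {
    counts <- table(endpoints$patient_id)
    keep_ids <- names(counts)[counts >= 4]
    return(endpoints[endpoints$patient_id %in% keep_ids, , drop = FALSE])
  }
  pts <- cohort$patients
  tr <- cohort$treatments
  start <- pts$cart_start[match(tr$patient_id, pts$patient_id)]
  tr_start_day <- as.numeric(tr$start - start)
  tr_stop_day <- as.numeric(tr$stop - start)
  ord <- order(tr$patient_id, tr_start_day)
  cutoff <- vapply(unique(endpoints$patient_id), function(id) {
    sel <- ord[tr$patient_id[ord] == id]
    if (!length(sel)) return(0)
    cls <- vapply(strsplit(tr$classes[sel], ",", fixed = TRUE),
                  function(z) paste(sort(z), collapse = ","), character(1))
    cut <- Inf
    if (length(sel) > 1) {
      changed <- which(cls[-1] != cls[1])
      if (length(changed))
        cut <- min(cut, tr_start_day[sel][changed[1] + 1])
      gaps <- tr_start_day[sel][-1] - tr_stop_day[sel][-length(sel)]
      gap_at <- which(gaps > max_gap_days)
      if (length(gap_at))
        cut <- min(cut, tr_stop_day[sel][gap_at[1]])
    }
    cut
  }, numeric(1))
  keep <- endpoints$t_days < cutoff[endpoints$patient_id]
  out <- endpoints[keep, , drop = FALSE]
  if (rule == "INITIAL_NNRTI") {
    nn <- pts$patient_id[pts$regimen_nnrti == 1L]
    out <- out[out$patient_id %in% nn, , drop = FALSE]
  }
  out
}
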