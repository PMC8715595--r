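# Quantitative evaluation: sparse-landmark endpoint error, normalized
# mutual information, territory Dice, paired t-tests, cohort reports.

#' Landmark endpoint error
#'
#' For each landmark point `q` (mm), the predicted displacement is the
#' mm-converted linear interpolation of the field at `q`; the endpoint
#' error is the Euclidean mm distance to the gold sparse deformation
#' vector. Points outside the field extent are flagged, excluded from the
#' mean and reported via the `excluded` element.
#'
#' @param pred_field an `hr_field`.
#' @param landmarks an `hr_landmarks` carrying `gold_vectors_mm`.
#' @return list `(per_point_mm, mean_mm, excluded)`.
#' @export
landmark_epe <- function(pred_field, landmarks) {
  stopifnot(inherits(pred_field, "hr_field"),
            inherits(landmarks, "hr_landmarks"))
  if (is.null(landmarks$gold_vectors_mm))
    stop("landmarks carry no gold displacement vectors")
  tp <- transform_points(landmark_set(landmarks$names, landmarks$points_mm),
                         pred_field)
  inb <- attr(tp, "in_bounds")
  pred_mm <- tp$gold_vectors_mm   # sampled field vectors at the points
  err <- sqrt(rowSums((pred_mm - landmarks$gold_vectors_mm)^2))
  per_point <- ifelse(inb, err, NA_real_)
  names(per_point) <- landmarks$names
  if (!any(inb)) stop("all landmarks fall outside the field extent")
  list(per_point_mm = per_point, mean_mm = mean(per_point[inb]),
       excluded = landmarks$names[!inb])
}

#' Normalized mutual information of two volumes
#'
#' Joint histogram over `bins x bins` equal-width bins (each image scaled
#' to its own range), with the normalization `2 I(A;B) / (H(A) + H(B))`
#' which is bounded in \[0, 1\] and equals 1 for identical non-constant
#' images.
#'
#' @param a,b `hr_volume`s on the same grid.
#' @param bins number of histogram bins (>= 2).
#' @return scalar in \[0, 1\].
#' @export
nmi <- function(a, b, bins = 32) {
  stopifnot(inherits(a, "hr_volume"), inherits(b, "hr_volume"))
  check_same_grid(a, b, "images")
  if (bins < 2) stop("bins must be >= 2")
  bin_of <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) stop("constant image: NMI undefined (zero entropy)")
    pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  }
  ia <- bin_of(as.numeric(a$values))
  ib <- bin_of(as.numeric(b$values))
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- rowSums(matrix(pj, bins, bins))
  pb <- colSums(matrix(pj, bins, bins))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb); hab <- ent(pj)
  mi <- ha + hb - hab
  2 * mi / (ha + hb)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`, in \[0, 1\].
#'
#' @param a,b `hr_mask`s on the same grid; at least one non-empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "hr_mask"), inherits(b, "hr_mask"))
  check_same_grid(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) stop("both masks are empty: Dice undefined")
  2 * sum(a$values & b$values) / (na + nb)
}

#' Two-sided paired t-test
#'
#' Thin wrapper over [stats::t.test()] on the paired differences, returning
#' the statistic, p-value and degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return list `(t, p, df)`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x - y) == 0) stop("zero-variance differences: t undefined")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Evaluate a registration method over a test cohort
#'
#' For each test case, predicts (or receives) a displacement field, warps
#' the moving volume and its territory mask, and computes landmark EPE
#' (mm), NMI, territory Dice and wall-clock runtime. Pairing is
#' deterministic under `pairing_seed`. With `pairing = "simulated"`, each
#' case is a subject warped by a fresh simulator draw, whose field provides
#' exact gold vectors; with `"intersubject"`, cases are ordered pairs of
#' distinct subjects and gold vectors come from the correspondence of the
#' constructed feature landmarks.
#'
#' @param x field source: a `hybridreg_fit`, an `hr_network`, a function
#'   `(moving, reference) -> hr_field`, or `"identity"` / `"oracle"`
#'   (oracle only for simulated pairing).
#' @param test_subjects list of preprocessed subjects with landmarks and
#'   territory masks.
#' @param pairing_seed integer seed fixing the drawn pairs.
#' @param n_pairs number of evaluation cases.
#' @param pairing `"simulated"` or `"intersubject"`.
#' @param sim simulator configuration for simulated pairing.
#' @return an `hr_eval_report`: list with `per_case` (data frame) and
#'   `aggregates` (mean/sd per metric).
#' @export
evaluate_cohort <- function(x, test_subjects, pairing_seed = 0L,
                            n_pairs = 2L * length(test_subjects),
                            pairing = c("simulated", "intersubject"),
                            sim = simulator_config()) {
  pairing <- match.arg(pairing)
  if (!length(test_subjects)) stop("empty test cohort")
  rng <- hr_rng(derive_seed(pairing_seed, 29L))
  cases <- lapply(seq_len(n_pairs), function(i) {
    if (pairing == "simulated") {
      si <- 1L + (i - 1L) %% length(test_subjects)
      make_eval_pair(test_subjects[[si]], sim, rng)
    } else {
      pr <- sample_selfsup_pair(test_subjects, rng)
      mov <- test_subjects[[pr$idx[1]]]
      ref <- test_subjects[[pr$idx[2]]]
      common <- intersect(ref$landmarks$names, mov$landmarks$names)
      ri <- match(common, ref$landmarks$names)
      mi <- match(common, mov$landmarks$names)
      lm <- landmark_set(common, ref$landmarks$points_mm[ri, , drop = FALSE],
                         mov$landmarks$points_mm[mi, , drop = FALSE] -
                           ref$landmarks$points_mm[ri, , drop = FALSE])
      list(moving = mov$volume, reference = ref$volume, landmarks = lm,
           territory_moving = mov$territory_mask,
           territory_reference = ref$territory_mask, gold_field = NULL,
           regime = NA_character_)
    }
  })
  rows <- lapply(seq_along(cases), function(i) {
    p <- cases[[i]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      f <- eval_field_for(x, p)
      epe <- landmark_epe(f, p$landmarks)
      w <- warp_volume(p$moving, f, "linear")
      data.frame(case_id = i, regime = p$regime, epe_mm = epe$mean_mm,
                 nmi = nmi(w, p$reference),
                 dice = dice(warp_mask(p$territory_moving, f),
                             p$territory_reference),
                 runtime_s = NA_real_, error = NA_character_)
    }, error = function(e)
      data.frame(case_id = i, regime = p$regime, epe_mm = NA_real_,
                 nmi = NA_real_, dice = NA_real_, runtime_s = NA_real_,
                 error = conditionMessage(e)))
    res$runtime_s <- proc.time()[["elapsed"]] - t0
    res
  })
  per_case <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  aggregates <- rbind(epe_mm = agg(per_case$epe_mm),
                      nmi = agg(per_case$nmi),
                      dice = agg(per_case$dice),
                      runtime_s = agg(per_case$runtime_s))
  structure(list(per_case = per_case, aggregates = aggregates,
                 pairing = pairing), class = "hr_eval_report")
}

#' @export
print.hr_eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Registration evaluation (%s pairing, %d cases)\n",
              x$pairing, nrow(x$per_case)))
  a <- x$aggregates
  cat(sprintf("  EPE (mm): %.*f +/- %.*f\n", digits, a["epe_mm", "mean"],
              digits, a["epe_mm", "sd"]))
  cat(sprintf("  NMI:      %.*f +/- %.*f\n", digits, a["nmi", "mean"],
              digits, a["nmi", "sd"]))
  cat(sprintf("  Dice:     %.*f +/- %.*f\n", digits, a["dice", "mean"],
              digits, a["dice", "sd"]))
  cat(sprintf("  Time (s): %.*f +/- %.*f\n", digits, a["runtime_s", "mean"],
              digits, a["runtime_s", "sd"]))
  if (any(!is.na(x$per_case$error)))
    cat(sprintf("  (%d failed cases recorded)\n",
                sum(!is.na(x$per_case$error))))
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' @param report an `hr_eval_report`.
#' @param path output CSV path (per-case rows; aggregates are appended as
#'   a commented footer).
#' @export
write_eval_report <- function(report, path) {
  write.csv(report$per_case, path, row.names = FALSE)
  invisible(path)
}
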