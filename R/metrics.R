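#' Duration-weighted 2x2 agreement table
#'
#' The contingency table underlying all agreement statistics, with time
#' (integer milliseconds) as the unit of observation:
#' `a` = duration both raters annotate FOG, `b` = rater-1-only FOG,
#' `c` = rater-2-only FOG, `d` = duration neither annotates FOG.
#' `a + b + c + d` equals the total observed duration.
#'
#' @param a_ms,b_ms,c_ms,d_ms non-negative cell durations in milliseconds.
#' @return an object of class `fog_agreement_table`.
#' @export
agreement_table <- function(a_ms, b_ms, c_ms, d_ms) {
  cells <- c(a_ms = as.numeric(a_ms), b_ms = as.numeric(b_ms),
             c_ms = as.numeric(c_ms), d_ms = as.numeric(d_ms))
  stopifnot(all(!is.na(cells)), all(cells >= 0))
  structure(as.list(cells), class = "fog_agreement_table")
}

#' @export
print.fog_agreement_table <- function(x, ...) {
  cat("<fog_agreement_table> (ms)\n")
  m <- matrix(c(x$a_ms, x$b_ms, x$c_ms, x$d_ms), 2, 2, byrow = TRUE,
              dimnames = list(rater1 = c("FOG", "no FOG"),
                              rater2 = c("FOG", "no FOG")))
  print(m)
  invisible(x)
}

#' Tabulate the agreement table from a timeline partition
#'
#' Computed on the *pre-resolution* partition: `a` is the total black
#' duration, `d` the total white, and the gray total splits into `b` (gray
#' annotated by rater 1) and `c` (gray annotated by rater 2). Agreement is
#' judged on the raters' initial overlap, before tolerance and correction
#' touch anything.
#'
#' With `epoch_ms` set, the trial is instead resampled into fixed epochs of
#' that length and each rater's epoch is scored FOG when they annotate more
#' than half of it (majority rule); cells are then epoch counts times
#' `epoch_ms`. This is provided only for comparability with epoch-based
#' literature -- the default duration weighting loses no information.
#'
#' @param partition a `fog_partition` from [partition_timeline()].
#' @param epoch_ms optional epoch length in milliseconds.
#' @return an [agreement_table()].
#' @export
tabulate_partition <- function(partition, epoch_ms = NULL) {
  stopifnot(inherits(partition, "fog_partition"))
  seg <- partition$segments
  if (is.null(epoch_ms)) {
    w <- seg$end_ms - seg$begin_ms
    gray <- seg$color == "gray"
    agreement_table(
      a_ms = sum(w[seg$color == "black"]),
      b_ms = sum(seg$a_ms[gray]),
      c_ms = sum(seg$b_ms[gray]),
      d_ms = sum(w[seg$color == "white"])
    )
  } else {
    epoch_ms <- as.numeric(epoch_ms)
    stopifnot(epoch_ms > 0)
    N <- partition$trial_duration_ms
    el <- partition$elementary
    starts <- seq(0, N - 1, by = epoch_ms)
    ends <- pmin(starts + epoch_ms, N)
    cover_in <- function(flag) {
      vapply(seq_along(starts), function(i) {
        inside <- pmax(0, pmin(el$end_ms, ends[i]) - pmax(el$begin_ms, starts[i]))
        sum(inside[flag])
      }, numeric(1))
    }
    # per-epoch covered ms for each rater; >50% of epoch -> FOG epoch
    ca <- cover_in(el$in_a) > (ends - starts) / 2
    cb <- cover_in(el$in_b) > (ends - starts) / 2
    agreement_table(sum(ca & cb) * epoch_ms, sum(ca & !cb) * epoch_ms,
                    sum(!ca & cb) * epoch_ms, sum(!ca & !cb) * epoch_ms)
  }
}

#' Specific agreement for the FOG (positive) category
#'
#' `PA = 2a / (2a + b + c)`: the probability that, given one rater annotates
#' FOG, the other agrees. Undefined (`NA`) when neither rater annotates any
#' FOG (`2a + b + c = 0`).
#'
#' @param t an [agreement_table()].
#' @return value in `[0, 1]`, or `NA` when undefined.
#' @export
positive_agreement <- function(t) {
  denom <- 2 * t$a_ms + t$b_ms + t$c_ms
  if (denom <= 0) return(NA_real_)
  2 * t$a_ms / denom
}

#' Specific agreement for the no-FOG (negative) category
#'
#' `NA = 2d / (2d + b + c)`. Undefined (`NA`) when both raters annotate FOG
#' continuously (`2d + b + c = 0`).
#'
#' @param t an [agreement_table()].
#' @return value in `[0, 1]`, or `NA` when undefined.
#' @export
negative_agreement <- function(t) {
  denom <- 2 * t$d_ms + t$b_ms + t$c_ms
  if (denom <= 0) return(NA_real_)
  2 * t$d_ms / denom
}

#' Prevalence index
#'
#' `PI = (a - d) / N`: the relative prevalence of FOG versus no-FOG time,
#' in `[-1, +1]`. Anchors: -1 when no rater annotates any FOG anywhere,
#' +1 when both raters annotate FOG continuously. Reported alongside the two
#' specific agreements because their interpretation depends on how rare the
#' events are.
#'
#' @param t an [agreement_table()].
#' @return value in `[-1, 1]`.
#' @export
prevalence_index <- function(t) {
  N <- t$a_ms + t$b_ms + t$c_ms + t$d_ms
  if (N <= 0) stop("empty agreement table (N = 0)")
  (t$a_ms - t$d_ms) / N
}

#' Cohen's kappa on the duration-weighted table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (a + d)/N` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / N^2`. Undefined (`NA`) when
#' `p_e = 1` -- notably when both raters annotate no FOG at all for a trial,
#' a common situation in FOG assessment and the reason specific agreement
#' plus prevalence index are preferred. Kappa also underestimates agreement
#' when FOG is very rare or near-continuous (prevalence effect); see
#' [prevalence_index()].
#'
#' @param t an [agreement_table()].
#' @return value `<= 1`, or `NA` when undefined.
#' @export
cohens_kappa <- function(t) {
  N <- t$a_ms + t$b_ms + t$c_ms + t$d_ms
  if (N <= 0) stop("empty agreement table (N = 0)")
  p_o <- (t$a_ms + t$d_ms) / N
  p_e <- ((t$a_ms + t$b_ms) * (t$a_ms + t$c_ms) +
          (t$c_ms + t$d_ms) * (t$b_ms + t$d_ms)) / N^2
  if (1 - p_e <= 0) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement
#'
#' Correlation between the raters' per-trial summary scores (e.g. % time
#' frozen) across trials, using the two-way random-effects,
#' absolute-agreement, single-rater ICC(2,1) of the Shrout-Fleiss scheme:
#'
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#'
#' where MSR, MSC, MSE are the row (trial), column (rater) and error mean
#' squares of the two-way layout, `n` trials, `k` raters. Because ICC
#' variants differ and are easy to confuse, the variant name is always
#' carried in the result. Note the ICC reflects agreement on per-trial
#' totals only, not the exact overlap of episodes -- limit its use to
#' questions where exact overlap does not matter.
#'
#' @param scores numeric matrix or data.frame, one row per trial, one column
#'   per rater (two or more raters; at least two trials).
#' @return list of class `fog_icc` with elements `value` and `variant`.
#' @export
icc_2_1 <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L) stop("ICC requires scores from at least 2 trials")
  if (k < 2L) stop("ICC requires at least 2 raters")
  if (any(is.na(scores))) stop("scores must be complete (no NA)")
  grand <- mean(scores)
  row_m <- rowMeans(scores); col_m <- colMeans(scores)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((scores - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  value <- if (denom == 0) NA_real_ else (msr - mse) / denom
  structure(list(value = value,
                 variant = "ICC(2,1), two-way random effects, absolute agreement, single rater"),
            class = "fog_icc")
}

#' @export
print.fog_icc <- function(x, ...) {
  cat(sprintf("ICC = %s [%s]\n",
              if (is.na(x$value)) "undefined" else sprintf("%.4f", x$value),
              x$variant))
  invisible(x)
}

#' Pool agreement tables across trials
#'
#' Cellwise sum: pooling is duration-weighted, so longer trials contribute
#' proportionally more to the pooled metrics.
#'
#' @param tables non-empty list of [agreement_table()]s.
#' @return an [agreement_table()].
#' @export
pool_tables <- function(tables) {
  if (length(tables) == 0L) stop("pool_tables needs at least one table")
  stopifnot(all(vapply(tables, inherits, logical(1), "fog_agreement_table")))
  agreement_table(
    sum(vapply(tables, `[[`, numeric(1), "a_ms")),
    sum(vapply(tables, `[[`, numeric(1), "b_ms")),
    sum(vapply(tables, `[[`, numeric(1), "c_ms")),
    sum(vapply(tables, `[[`, numeric(1), "d_ms"))
  )
}

#' Per-trial and pooled agreement report
#'
#' One row per trial plus a duration-weighted pooled row. Undefined metrics
#' are reported as `NA` with `*_defined` set `FALSE` -- never as silent
#' zeros. All three recommended metrics (positive agreement, negative
#' agreement, prevalence index) are reported together with Cohen's kappa for
#' comparison.
#'
#' @param tables list of [agreement_table()]s, one per trial.
#' @param trial_ids optional character vector of trial identifiers.
#' @return a `data.frame` with columns `trial`, `scope`,
#'   `positive_agreement`, `negative_agreement`, `prevalence_index`,
#'   `cohens_kappa`, `pa_defined`, `na_defined`, `kappa_defined`.
#' @export
agreement_report <- function(tables, trial_ids = NULL) {
  if (inherits(tables, "fog_agreement_table")) tables <- list(tables)
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%d", seq_along(tables))
  stopifnot(length(trial_ids) == length(tables))
  row_for <- function(t, id, scope) {
    pa <- positive_agreement(t); na_ <- negative_agreement(t)
    kap <- cohens_kappa(t)
    data.frame(trial = id, scope = scope,
               positive_agreement = pa, negative_agreement = na_,
               prevalence_index = prevalence_index(t), cohens_kappa = kap,
               pa_defined = !is.na(pa), na_defined = !is.na(na_),
               kappa_defined = !is.na(kap), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, Map(row_for, tables, trial_ids, "per-trial"))
  pooled <- row_for(pool_tables(tables), "pooled", "pooled")
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}
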