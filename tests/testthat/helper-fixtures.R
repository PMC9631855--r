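# Programmatic fixtures: nothing on disk, everything seeded.

fog_trigger_set <- c("FOG_Target", "FOG_180_R", "FOG_Doorway")

# random normalized track: k disjoint, non-abutting episodes from distinct
# sorted boundary points
random_track <- function(id, N, max_eps = 4) {
  k <- sample(0:max_eps, 1L)
  if (k == 0L) return(fog_track(NULL, id, "t", N))
  pts <- sort(sample.int(N + 1L, 2L * k) - 1L)
  fog_track(data.frame(
    begin_ms = pts[seq(1L, 2L * k, by = 2L)],
    end_ms = pts[seq(2L, 2L * k, by = 2L)],
    phenotype = sample(fog_phenotypes, k, replace = TRUE),
    trigger = sample(fog_trigger_set, k, replace = TRUE)
  ), id, "t", N)
}

random_pair <- function(seed, trial_range = c(8000L, 20000L), max_eps = 4) {
  set.seed(seed)
  N <- sample(seq(trial_range[1L], trial_range[2L], by = 500L), 1L)
  list(a = random_track("r1", N, max_eps), b = random_track("r2", N, max_eps), N = N)
}

# hand-built trial mirroring the canonical two-rater comparison figure:
# a leading short gray (preceding), an enclosed short gray, a trailing long
# gray (> 2 s), and one isolated episode seen by rater 1 only
fig2_tracks <- function() {
  a <- fog_track(data.frame(
    begin_ms = c(1000, 8000, 15000, 25000),
    end_ms = c(5000, 12000, 18000, 26000),
    phenotype = c("trembling", "shuffling", "akinesia", "trembling"),
    trigger = c("FOG_Target", "FOG_Doorway", "FOG_180_R", "FOG_Target")
  ), "r1", "t", 30000)
  b <- fog_track(data.frame(
    begin_ms = c(2000, 8000, 10000, 15000),
    end_ms = c(5000, 9500, 12000, 21000),
    phenotype = c("trembling", "shuffling", "akinesia", "akinesia"),
    trigger = c("FOG_Target", "FOG_Doorway", "FOG_Doorway", "FOG_Doorway")
  ), "r2", "t", 30000)
  list(a = a, b = b)
}

# vector-based reference metrics from a 2x2 duration table (cells in `unit`
# ms chunks so the vectors stay small); independent of the package formulas
ref_metrics <- function(a, b, c, d, unit = 1) {
  stopifnot((c(a, b, c, d) %% unit) == 0)
  r1 <- rep(c(1L, 1L, 0L, 0L), times = c(a, b, c, d) / unit)
  r2 <- rep(c(1L, 0L, 1L, 0L), times = c(a, b, c, d) / unit)
  p1 <- mean(r1); p2 <- mean(r2)
  p_o <- mean(r1 == r2)
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  list(
    pa = 2 * sum(r1 & r2) / (sum(r1) + sum(r2)),
    na = 2 * sum(!r1 & !r2) / (sum(!r1) + sum(!r2)),
    pi = mean(r1 & r2) - mean(!r1 & !r2),
    kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  )
}

# ICC(2,1) reference: mean squares from aov(), Shrout-Fleiss composition
ref_icc_2_1 <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  df <- data.frame(score = as.vector(scores),
                   trial = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- stats::anova(stats::aov(score ~ trial + rater, data = df))[["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
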