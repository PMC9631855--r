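#' Specification of a simulated two-rater annotation experiment
#'
#' Describes a ground-truth stream of FOG episodes and the imperfections of
#' the raters observing it. The simulator emulates the disagreement modes
#' seen between human video raters: boundary imprecision (one rater starts
#' annotating the same episode half a second before the other), episodes
#' seen by only one rater, one long episode annotated by the other rater as
#' multiple short epochs, and phenotype/trigger mislabelling.
#'
#' Defaults describe a plausible gait-lab trial: a 60 s walking course with
#' 5 episodes of ~3 s mean duration (log-normal, so a heavy right tail of
#' long freezes), ~6 s mean gaps, 300 ms boundary jitter (well under the
#' half-second imprecision considered unremarkable), and a 10% chance each
#' of a rater missing an episode, splitting one, or mislabelling it.
#'
#' @param trial_duration_ms trial length (default 60000).
#' @param n_episodes number of true episodes (default 5).
#' @param episode_mean_ms mean true episode duration (default 3000);
#'   durations are log-normal with `episode_sdlog` (default 0.4).
#' @param episode_sdlog log-scale sd of episode durations.
#' @param gap_mean_ms mean inter-episode gap (default 6000); gaps are
#'   log-normal with `gap_sdlog` (default 0.5).
#' @param gap_sdlog log-scale sd of gaps.
#' @param boundary_jitter_sd_ms sd of the truncated-normal jitter applied to
#'   each rater's episode boundaries (default 300).
#' @param p_miss probability a rater misses a true episode entirely.
#' @param p_split probability a rater splits a true episode into two epochs
#'   separated by a short gap.
#' @param label_confusion_rate probability a rater mislabels an episode's
#'   phenotype (and, independently, its trigger).
#' @param rng_seed integer seed; identical seeds give identical simulations.
#' @return a list of class `fog_sim_spec`.
#' @export
simulation_spec <- function(trial_duration_ms = 60000, n_episodes = 5,
                            episode_mean_ms = 3000, episode_sdlog = 0.4,
                            gap_mean_ms = 6000, gap_sdlog = 0.5,
                            boundary_jitter_sd_ms = 300,
                            p_miss = 0.1, p_split = 0.1,
                            label_confusion_rate = 0.1,
                            rng_seed = 1L) {
  spec <- list(trial_duration_ms = as.numeric(trial_duration_ms),
               n_episodes = as.integer(n_episodes),
               episode_mean_ms = as.numeric(episode_mean_ms),
               episode_sdlog = as.numeric(episode_sdlog),
               gap_mean_ms = as.numeric(gap_mean_ms),
               gap_sdlog = as.numeric(gap_sdlog),
               boundary_jitter_sd_ms = as.numeric(boundary_jitter_sd_ms),
               p_miss = as.numeric(p_miss), p_split = as.numeric(p_split),
               label_confusion_rate = as.numeric(label_confusion_rate),
               rng_seed = as.integer(rng_seed))
  with(spec, stopifnot(
    trial_duration_ms > 0, n_episodes >= 0,
    episode_mean_ms > 0, episode_sdlog >= 0,
    gap_mean_ms > 0, gap_sdlog >= 0, boundary_jitter_sd_ms >= 0,
    p_miss >= 0, p_miss <= 1, p_split >= 0, p_split <= 1,
    label_confusion_rate >= 0, label_confusion_rate <= 1
  ))
  structure(spec, class = "fog_sim_spec")
}

fog_triggers <- c("FOG_Target", "FOG_180_R", "FOG_Doorway")

# log-normal draw with a target arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  if (sdlog == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a ground-truth FOG episode stream
#'
#' Draws `n_episodes` disjoint episodes with log-normal durations separated
#' by log-normal gaps, labelled with phenotypes and triggers drawn uniformly
#' from the standard label sets. Deterministic under `rng_seed`. When a
#' random layout does not fit in the trial it is redrawn (up to 100 times,
#' within the same seeded stream); a spec that cannot possibly fit errors
#' immediately.
#'
#' @param spec a [simulation_spec()].
#' @return a [fog_track()] with `rater_id = "truth"`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "fog_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_episodes
  if (n == 0L) {
    return(fog_track(NULL, "truth", "sim", spec$trial_duration_ms))
  }
  # hard infeasibility: even 1 ms episodes with 1 ms gaps cannot fit
  if (2 * n > spec$trial_duration_ms) {
    stop("infeasible simulation spec: episodes cannot fit in the trial")
  }
  for (attempt in seq_len(100L)) {
    dur <- pmax(200, round(rlnorm_mean(n, spec$episode_mean_ms, spec$episode_sdlog)))
    gap <- pmax(200, round(rlnorm_mean(n + 1L, spec$gap_mean_ms, spec$gap_sdlog)))
    if (sum(dur) + sum(gap) <= spec$trial_duration_ms) {
      begin <- cumsum(gap[seq_len(n)]) + c(0, cumsum(dur[-n]))
      eps <- new_episode_frame(
        begin, begin + dur,
        sample(fog_phenotypes, n, replace = TRUE),
        sample(fog_triggers, n, replace = TRUE)
      )
      return(fog_track(eps, "truth", "sim", spec$trial_duration_ms))
    }
  }
  stop("infeasible simulation spec: episodes cannot fit in the trial (100 layouts tried)")
}

#' Simulate one imperfect rater observing a ground-truth track
#'
#' Each true episode is independently missed with probability `p_miss`;
#' surviving episodes get truncated-normal boundary jitter (clipped so the
#' episode keeps positive length and stays inside the trial), are split into
#' two epochs with probability `p_split`, and have phenotype/trigger
#' confused with an alternative label at `label_confusion_rate`. The output
#' is normalized. The attributes `missed` and `split` (logical, one entry
#' per truth episode) record which imperfections were injected, so tests can
#' compare against known ground truth.
#'
#' Uses the seed `spec$rng_seed + 7919 * rater_index`, so the two raters are
#' independent of each other and of the truth stream yet fully reproducible.
#'
#' @param truth the [generate_truth()] output.
#' @param spec the [simulation_spec()] used for the truth.
#' @param rater_id identifier for the simulated rater.
#' @param rater_index small integer distinguishing the raters' random
#'   streams (1 and 2 for the usual pair).
#' @return a normalized [fog_track()].
#' @export
simulate_rater <- function(truth, spec, rater_id = "rater1", rater_index = 1L) {
  stopifnot(inherits(truth, "fog_track"), inherits(spec, "fog_sim_spec"))
  set.seed(spec$rng_seed + 7919L * as.integer(rater_index))
  N <- truth$trial_duration_ms
  te <- truth$episodes
  n <- nrow(te)
  missed <- logical(n); split <- logical(n)
  out <- new_episode_frame()
  for (i in seq_len(n)) {
    if (stats::runif(1) < spec$p_miss) { missed[i] <- TRUE; next }
    b <- te$begin_ms[i] + round(stats::rnorm(1, 0, spec$boundary_jitter_sd_ms))
    e <- te$end_ms[i] + round(stats::rnorm(1, 0, spec$boundary_jitter_sd_ms))
    b <- max(0, min(b, N - 1))
    e <- max(b + 1, min(e, N))
    phen <- te$phenotype[i]; trig <- te$trigger[i]
    if (stats::runif(1) < spec$label_confusion_rate) {
      phen <- sample(setdiff(fog_phenotypes, phen), 1L)
    }
    if (stats::runif(1) < spec$label_confusion_rate) {
      trig <- sample(setdiff(fog_triggers, trig), 1L)
    }
    dur <- e - b
    if (stats::runif(1) < spec$p_split && dur >= 1000) {
      # split around the midpoint with a short gap (200..min(800, dur/3) ms)
      gap <- round(stats::runif(1, 200, max(201, min(800, dur / 3))))
      mid <- b + round(dur / 2)
      split[i] <- TRUE
      out <- rbind(out, new_episode_frame(c(b, mid + gap %/% 2 + gap %% 2),
                                          c(mid - gap %/% 2, e),
                                          rep(phen, 2), rep(trig, 2)))
    } else {
      out <- rbind(out, new_episode_frame(b, e, phen, trig))
    }
  }
  track <- normalize_track(fog_track(out, rater_id, truth$trial_id, N))
  attr(track, "missed") <- missed
  attr(track, "split") <- split
  track
}
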