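#' @keywords internal
#' @importFrom utils head
"_PACKAGE"

#' Recognised FOG phenotype labels
#'
#' The three phenotype labels used when characterising a freezing episode,
#' plus the `"unspecified"` sentinel used whenever a label is absent or
#' conflicting.
#'
#' @export
fog_phenotypes <- c("trembling", "shuffling", "akinesia")

#' @rdname fog_phenotypes
#' @export
fog_unspecified <- "unspecified"

new_episode_frame <- function(begin_ms = integer(), end_ms = integer(),
                              phenotype = character(), trigger = character()) {
  data.frame(
    begin_ms = as.numeric(begin_ms),
    end_ms = as.numeric(end_ms),
    phenotype = as.character(phenotype),
    trigger = as.character(trigger),
    stringsAsFactors = FALSE
  )
}

#' One rater's annotation track for a single trial
#'
#' A `fog_track` holds one rater's FOG episodes for one video trial.
#' Episodes are half-open intervals `[begin_ms, end_ms)` in integer
#' milliseconds from trial start; abutting episodes therefore do not overlap
#' and durations are additive. Each episode carries a phenotype label
#' (one of [fog_phenotypes] or `"unspecified"`) and a free-text trigger label
#' (e.g. `"FOG_Doorway"`, or `"unspecified"`).
#'
#' The constructor sorts episodes by begin time and validates basic
#' invariants (`begin_ms >= 0`, `end_ms > begin_ms`, episodes inside the
#' trial). Within-rater overlaps are permitted here; call [normalize_track()]
#' before comparing two raters.
#'
#' @param episodes `data.frame` with columns `begin_ms`, `end_ms` and
#'   optionally `phenotype`, `trigger`; or `NULL` for an empty track.
#' @param rater_id,trial_id identifiers carried through all outputs.
#' @param trial_duration_ms total observed duration of the trial in
#'   milliseconds. If `NULL`, the maximum episode end time is used (0 for an
#'   empty track); this is only a fallback -- the observation duration is the
#'   denominator of the negative-agreement statistic and should be supplied
#'   when known.
#' @return An object of class `fog_track`: a list with fields `rater_id`,
#'   `trial_id`, `episodes` and `trial_duration_ms`.
#' @seealso [normalize_track()], [partition_timeline()]
#' @export
fog_track <- function(episodes = NULL, rater_id = "rater", trial_id = "trial",
                      trial_duration_ms = NULL) {
  if (is.null(episodes) || nrow(as.data.frame(episodes)) == 0L) {
    episodes <- new_episode_frame()
  } else {
    episodes <- as.data.frame(episodes, stringsAsFactors = FALSE)
    if (!all(c("begin_ms", "end_ms") %in% names(episodes))) {
      stop("episodes must have columns 'begin_ms' and 'end_ms'")
    }
    if (is.null(episodes$phenotype)) episodes$phenotype <- fog_unspecified
    if (is.null(episodes$trigger)) episodes$trigger <- fog_unspecified
    episodes <- new_episode_frame(episodes$begin_ms, episodes$end_ms,
                                  episodes$phenotype, episodes$trigger)
    if (any(is.na(episodes$begin_ms)) || any(is.na(episodes$end_ms))) {
      stop("episode times must not be NA")
    }
    if (any(episodes$begin_ms < 0)) stop("episode begin_ms must be >= 0")
    bad <- which(episodes$end_ms <= episodes$begin_ms)
    if (length(bad)) {
      stop(sprintf("episode %d has end_ms <= begin_ms (zero-length episodes are rejected)",
                   bad[1L]))
    }
    episodes <- episodes[order(episodes$begin_ms, episodes$end_ms), , drop = FALSE]
    rownames(episodes) <- NULL
  }
  if (is.null(trial_duration_ms)) {
    trial_duration_ms <- if (nrow(episodes)) max(episodes$end_ms) else 0
  }
  trial_duration_ms <- as.numeric(trial_duration_ms)
  if (nrow(episodes) && any(episodes$end_ms > trial_duration_ms)) {
    stop("episodes must end at or before trial_duration_ms")
  }
  structure(
    list(rater_id = as.character(rater_id), trial_id = as.character(trial_id),
         episodes = episodes, trial_duration_ms = trial_duration_ms),
    class = "fog_track"
  )
}

#' @export
print.fog_track <- function(x, ...) {
  cat(sprintf("<fog_track> rater '%s', trial '%s': %d episode(s), %.3f s observed\n",
              x$rater_id, x$trial_id, nrow(x$episodes), x$trial_duration_ms / 1000))
  if (nrow(x$episodes)) print(x$episodes)
  invisible(x)
}

#' Merge overlapping or abutting episodes within one rater's track
#'
#' Raters occasionally leave sloppy annotations: two episodes that overlap or
#' touch. The comparison procedure presupposes each rater contributes a set of
#' disjoint, non-touching episodes, so overlapping or abutting same-rater
#' episodes are merged into one before the two raters are compared. When the
#' merged episodes disagree on phenotype or trigger, the merged episode gets
#' `"unspecified"` for that label and a warning is raised.
#'
#' @param track a [fog_track()].
#' @return A `fog_track` whose episodes are disjoint and non-abutting.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "fog_track"))
  eps <- track$episodes
  if (nrow(eps) <= 1L) return(track)
  out <- eps[1L, , drop = FALSE]
  for (i in seq_len(nrow(eps))[-1L]) {
    j <- nrow(out)
    if (eps$begin_ms[i] <= out$end_ms[j]) {  # overlap or abutment
      out$end_ms[j] <- max(out$end_ms[j], eps$end_ms[i])
      if (!identical(out$phenotype[j], eps$phenotype[i])) {
        warning(sprintf("rater '%s': merged episodes disagree on phenotype ('%s' vs '%s'); set to unspecified",
                        track$rater_id, out$phenotype[j], eps$phenotype[i]))
        out$phenotype[j] <- fog_unspecified
      }
      if (!identical(out$trigger[j], eps$trigger[i])) {
        warning(sprintf("rater '%s': merged episodes disagree on trigger ('%s' vs '%s'); set to unspecified",
                        track$rater_id, out$trigger[j], eps$trigger[i]))
        out$trigger[j] <- fog_unspecified
      }
    } else {
      out <- rbind(out, eps[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  track$episodes <- out
  track
}

# TRUE when the track satisfies the normalized invariants (disjoint,
# non-abutting, sorted, inside the trial).
is_normalized <- function(track) {
  eps <- track$episodes
  if (nrow(eps) <= 1L) return(TRUE)
  all(eps$begin_ms[-1L] > eps$end_ms[-nrow(eps)])
}
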