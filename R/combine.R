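#' Combining parameters: tolerance and correction
#'
#' The two parameters that govern how non-isolated gray areas (timeline
#' segments annotated as FOG by exactly one rater, bordering an agreed-FOG
#' segment) are resolved:
#'
#' * `tolerance_ms` -- the duration threshold separating minor annotation
#'   imprecision from substantive disagreement. A non-isolated gray segment
#'   strictly longer than the tolerance goes to third-rater discussion; one of
#'   the tolerance or shorter is resolved by the correction. The default,
#'   2000 ms, follows the convention that a FOG episode ends once the
#'   participant performs two effective alternating steps (roughly 2 s).
#'   `Inf` is allowed (nothing non-isolated is ever discussed).
#' * `correction` -- `"exclude"` (default; only certain FOG is counted, the
#'   conservative choice for fundamental research) counts short non-isolated
#'   grays as no-FOG; `"include"` (for e.g. on-demand cueing development,
#'   where every potential FOG epoch matters) absorbs them into the bordering
#'   agreed-FOG episode.
#'
#' Isolated gray segments (annotated by only one rater and not bordering any
#' agreed FOG) always go to discussion, regardless of both parameters.
#'
#' @param tolerance_ms non-negative number of milliseconds (may be `Inf`).
#' @param correction `"exclude"` or `"include"`.
#' @return a list of class `fog_config`.
#' @export
combine_config <- function(tolerance_ms = 2000, correction = c("exclude", "include")) {
  correction <- match.arg(correction)
  tolerance_ms <- as.numeric(tolerance_ms)
  stopifnot(length(tolerance_ms) == 1L, !is.na(tolerance_ms), tolerance_ms >= 0)
  structure(list(tolerance_ms = tolerance_ms, correction = correction),
            class = "fog_config")
}

# label summary for a set of covering episodes: the unique label if there is
# exactly one, NA if none cover, "unspecified" if they conflict
collapse_label <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  if (length(u) == 0L) NA_character_ else if (length(u) == 1L) u else fog_unspecified
}

#' Partition a trial timeline into black, white and gray segments
#'
#' Compares two normalized rater tracks over the same trial and returns the
#' unique maximal-segment partition of `[0, trial_duration_ms)` into:
#'
#' * **black** -- both raters annotate FOG (definite FOG),
#' * **white** -- neither does (definite no-FOG),
#' * **gray** -- exactly one does (a possible FOG episode, the unit of
#'   disagreement the procedure resolves).
#'
#' Segments are contiguous, cover the trial exactly, and adjacent segments
#' differ in colour (each segment is maximal). Each segment also records how
#' many of its milliseconds each rater covers (`a_ms`, `b_ms`; for a gray
#' segment these partition its width and identify the annotating rater) and
#' the per-rater phenotype/trigger labels covering it. Gray segments are
#' classified by [classify_gray()], which is called automatically.
#'
#' @param a,b normalized [fog_track()]s with identical `trial_id` and
#'   `trial_duration_ms`.
#' @return an object of class `fog_partition`: list with `trial_id`,
#'   `trial_duration_ms`, `rater_ids`, and a `segments` data.frame.
#' @export
partition_timeline <- function(a, b) {
  stopifnot(inherits(a, "fog_track"), inherits(b, "fog_track"))
  if (!identical(a$trial_id, b$trial_id)) {
    stop(sprintf("trial_id mismatch: '%s' vs '%s'", a$trial_id, b$trial_id))
  }
  if (!isTRUE(all.equal(a$trial_duration_ms, b$trial_duration_ms))) {
    stop("trial_duration_ms mismatch between raters")
  }
  if (!is_normalized(a) || !is_normalized(b)) {
    stop("tracks must be normalized (see normalize_track) before partitioning")
  }
  N <- a$trial_duration_ms
  if (N <= 0) stop("trial_duration_ms must be positive")
  ea <- a$episodes; eb <- b$episodes
  cuts <- sort(unique(c(0, N, ea$begin_ms, ea$end_ms, eb$begin_ms, eb$end_ms)))
  begin <- cuts[-length(cuts)]; end <- cuts[-1L]

  cover_idx <- function(eps, t) {
    # index of the episode covering instant t, or NA (episodes disjoint)
    if (nrow(eps) == 0L) return(rep(NA_integer_, length(t)))
    vapply(t, function(x) {
      i <- which(eps$begin_ms <= x & x < eps$end_ms)
      if (length(i)) i[1L] else NA_integer_
    }, integer(1))
  }
  ia <- cover_idx(ea, begin); ib <- cover_idx(eb, begin)
  inA <- !is.na(ia); inB <- !is.na(ib)
  color <- ifelse(inA & inB, "black", ifelse(inA | inB, "gray", "white"))

  elem <- data.frame(
    begin_ms = begin, end_ms = end, color = color,
    a_ms = ifelse(inA, end - begin, 0), b_ms = ifelse(inB, end - begin, 0),
    a_phenotype = ifelse(inA, ea$phenotype[ia], NA_character_),
    a_trigger = ifelse(inA, ea$trigger[ia], NA_character_),
    b_phenotype = ifelse(inB, eb$phenotype[ib], NA_character_),
    b_trigger = ifelse(inB, eb$trigger[ib], NA_character_),
    stringsAsFactors = FALSE
  )

  # merge runs of equal colour into maximal segments
  runs <- rle(elem$color)
  stops <- cumsum(runs$lengths); starts <- c(1L, head(stops, -1L) + 1L)
  seg <- do.call(rbind, lapply(seq_along(starts), function(r) {
    block <- elem[starts[r]:stops[r], , drop = FALSE]
    data.frame(
      begin_ms = block$begin_ms[1L], end_ms = block$end_ms[nrow(block)],
      color = runs$values[r],
      gray_class = "not-applicable",
      a_ms = sum(block$a_ms), b_ms = sum(block$b_ms),
      a_phenotype = collapse_label(block$a_phenotype),
      a_trigger = collapse_label(block$a_trigger),
      b_phenotype = collapse_label(block$b_phenotype),
      b_trigger = collapse_label(block$b_trigger),
      stringsAsFactors = FALSE
    )
  }))
  rownames(seg) <- NULL
  p <- structure(
    list(trial_id = a$trial_id, trial_duration_ms = N,
         rater_ids = c(a$rater_id, b$rater_id), segments = seg,
         # pre-merge elementary intervals with exact per-rater coverage;
         # needed for epoch resampling where maximal gray segments can mix
         # the two raters
         elementary = data.frame(begin_ms = begin, end_ms = end,
                                 in_a = inA, in_b = inB)),
    class = "fog_partition"
  )
  classify_gray(p)
}

#' Classify gray segments as isolated or bordering agreed FOG
#'
#' A gray segment is *isolated* when it does not touch an agreed-FOG (black)
#' segment on either side -- an episode only one rater saw, which must always
#' be discussed. Otherwise it is non-isolated: `"preceding"` (black
#' immediately after), `"following"` (black immediately before) or
#' `"enclosed"` (black on both sides). Adjacency means zero-gap abutment;
#' discussion-bound grays never count as "definite FOG" neighbours, only
#' black segments do.
#'
#' @param partition a `fog_partition` from [partition_timeline()].
#' @return the partition with `gray_class` filled in.
#' @export
classify_gray <- function(partition) {
  stopifnot(inherits(partition, "fog_partition"))
  seg <- partition$segments
  n <- nrow(seg)
  for (i in seq_len(n)) {
    if (seg$color[i] != "gray") next
    before <- i > 1L && seg$color[i - 1L] == "black"
    after <- i < n && seg$color[i + 1L] == "black"
    seg$gray_class[i] <-
      if (before && after) "enclosed"
      else if (after) "preceding"
      else if (before) "following"
      else "isolated"
  }
  partition$segments <- seg
  partition
}

#' @export
print.fog_partition <- function(x, ...) {
  cat(sprintf("<fog_partition> trial '%s' (%.3f s), raters %s vs %s\n",
              x$trial_id, x$trial_duration_ms / 1000,
              x$rater_ids[1L], x$rater_ids[2L]))
  print(x$segments[, c("begin_ms", "end_ms", "color", "gray_class")])
  invisible(x)
}

#' Resolve a partition into agreed FOG, agreed no-FOG and discussion segments
#'
#' Applies the tolerance/correction procedure to a classified partition:
#'
#' * black -> `FOG`; white -> `no_FOG`;
#' * isolated gray -> `discussion`, always, regardless of length;
#' * non-isolated gray strictly longer than `tolerance_ms` -> `discussion`;
#' * non-isolated gray of the tolerance or shorter -> `FOG` when
#'   `correction = "include"`, else `no_FOG`. (A gray of exactly the
#'   tolerance is resolvable: only *longer than* the tolerance is discussed.)
#'
#' A gray segment resolved to FOG inherits phenotype and trigger from its
#' bordering black segment (for an enclosed gray, from the earlier one).
#' Black segments carry the label the two raters agree on, or
#' `"unspecified"` when they differ (the disagreement itself is flagged later
#' by [flag_label_disagreements()]).
#'
#' @param partition a `fog_partition` with gray classes assigned.
#' @param config a [combine_config()].
#' @return a `data.frame` of resolved segments with columns `begin_ms`,
#'   `end_ms`, `outcome` (`FOG` / `no_FOG` / `discussion`), `provenance`,
#'   `phenotype`, `trigger`, `check_type`, `check_trigger`.
#' @export
resolve_partition <- function(partition, config = combine_config()) {
  stopifnot(inherits(partition, "fog_partition"), inherits(config, "fog_config"))
  seg <- partition$segments
  n <- nrow(seg)

  agreed <- function(i, what) {
    av <- seg[[paste0("a_", what)]][i]; bv <- seg[[paste0("b_", what)]][i]
    if (!is.na(av) && !is.na(bv) && identical(av, bv)) av else fog_unspecified
  }
  own <- function(i, what) {
    # label of whichever rater annotated a gray segment
    collapse_label(c(seg[[paste0("a_", what)]][i], seg[[paste0("b_", what)]][i]))
  }

  outcome <- character(n); provenance <- character(n)
  phenotype <- character(n); trigger <- character(n)
  for (i in seq_len(n)) {
    if (seg$color[i] == "black") {
      outcome[i] <- "FOG"; provenance[i] <- "black"
      phenotype[i] <- agreed(i, "phenotype"); trigger[i] <- agreed(i, "trigger")
    } else if (seg$color[i] == "white") {
      outcome[i] <- "no_FOG"; provenance[i] <- "white"
      phenotype[i] <- fog_unspecified; trigger[i] <- fog_unspecified
    } else {
      width <- seg$end_ms[i] - seg$begin_ms[i]
      if (seg$gray_class[i] == "isolated") {
        outcome[i] <- "discussion"; provenance[i] <- "gray-isolated→discussion"
        phenotype[i] <- own(i, "phenotype"); trigger[i] <- own(i, "trigger")
      } else if (width > config$tolerance_ms) {
        outcome[i] <- "discussion"; provenance[i] <- "gray-long→discussion"
        phenotype[i] <- own(i, "phenotype"); trigger[i] <- own(i, "trigger")
      } else if (config$correction == "include") {
        outcome[i] <- "FOG"; provenance[i] <- "gray-included"
        donor <- switch(seg$gray_class[i],
                        preceding = i + 1L,
                        following = i - 1L,
                        enclosed = i - 1L)  # earlier black neighbour
        phenotype[i] <- agreed(donor, "phenotype")
        trigger[i] <- agreed(donor, "trigger")
      } else {
        outcome[i] <- "no_FOG"; provenance[i] <- "gray-excluded→no_FOG"
        phenotype[i] <- fog_unspecified; trigger[i] <- fog_unspecified
      }
    }
  }
  data.frame(begin_ms = seg$begin_ms, end_ms = seg$end_ms,
             outcome = outcome, provenance = provenance,
             phenotype = phenotype, trigger = trigger,
             check_type = FALSE, check_trigger = FALSE,
             stringsAsFactors = FALSE)
}

#' Merge resolved FOG segments into combined episodes
#'
#' Maximal runs of contiguous `outcome == "FOG"` resolved segments become
#' single combined episodes -- so an enclosed gray resolved to FOG fuses its
#' two black neighbours into one episode, while the same gray resolved to
#' no-FOG leaves them as two. Flags propagate by union; a run whose segments
#' disagree on phenotype or trigger gets `"unspecified"` for that label.
#'
#' @param resolved resolved-segment `data.frame` from [resolve_partition()].
#' @return a `data.frame` of combined episodes with columns `begin_ms`,
#'   `end_ms`, `phenotype`, `trigger`, `check_type`, `check_trigger`.
#' @export
merge_episodes <- function(resolved) {
  out <- new_episode_frame()
  out$check_type <- logical(0); out$check_trigger <- logical(0)
  if (nrow(resolved) == 0L) return(out)
  is_fog <- resolved$outcome == "FOG"
  runs <- rle(is_fog)
  stops <- cumsum(runs$lengths); starts <- c(1L, head(stops, -1L) + 1L)
  for (r in which(runs$values)) {
    block <- resolved[starts[r]:stops[r], , drop = FALSE]
    lab <- function(col) {
      u <- unique(block[[col]])
      if (length(u) == 1L) u else fog_unspecified
    }
    out <- rbind(out, data.frame(
      begin_ms = block$begin_ms[1L], end_ms = block$end_ms[nrow(block)],
      phenotype = lab("phenotype"), trigger = lab("trigger"),
      check_type = any(block$check_type), check_trigger = any(block$check_trigger),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Flag combined episodes where the raters disagree on phenotype or trigger
#'
#' For each combined episode, collects the phenotype (and trigger) labels of
#' every episode of each rater overlapping it. When the two raters' label
#' sets differ the episode is flagged `check_type` (phenotypes) or
#' `check_trigger` (triggers) for review; when both raters used one and the
#' same label, the episode carries that label.
#'
#' @param a,b the normalized [fog_track()]s the episodes were derived from.
#' @param episodes combined-episode `data.frame` from [merge_episodes()].
#' @return `episodes` with flags and labels updated.
#' @export
flag_label_disagreements <- function(a, b, episodes) {
  stopifnot(inherits(a, "fog_track"), inherits(b, "fog_track"))
  if (nrow(episodes) == 0L) return(episodes)
  overlapping <- function(eps, lo, hi) {
    eps[eps$begin_ms < hi & eps$end_ms > lo, , drop = FALSE]
  }
  for (k in seq_len(nrow(episodes))) {
    oa <- overlapping(a$episodes, episodes$begin_ms[k], episodes$end_ms[k])
    ob <- overlapping(b$episodes, episodes$begin_ms[k], episodes$end_ms[k])
    pa <- unique(oa$phenotype); pb <- unique(ob$phenotype)
    if (!setequal(pa, pb)) {
      episodes$check_type[k] <- TRUE
    } else if (length(pa) == 1L) {
      episodes$phenotype[k] <- pa
    }
    ta <- unique(oa$trigger); tb <- unique(ob$trigger)
    if (!setequal(ta, tb)) {
      episodes$check_trigger[k] <- TRUE
    } else if (length(ta) == 1L) {
      episodes$trigger[k] <- ta
    }
  }
  episodes
}

#' Combine two raters' annotations of one trial
#'
#' Runs the full procedure: normalize both tracks, partition the timeline
#' into black/white/gray, classify the gray segments, resolve them with the
#' tolerance and correction parameters, merge agreed-FOG runs into combined
#' episodes, and flag phenotype/trigger disagreements. The interrater
#' agreement table is tabulated from the *pre-resolution* partition, since
#' the initial overlap -- not the corrected outcome -- is what reflects
#' rater reliability.
#'
#' @param a,b [fog_track()]s for the two raters (normalized internally).
#' @param config a [combine_config()].
#' @return an object of class `fog_combined`: list with `trial_id`,
#'   `config`, `partition`, `resolved`, `episodes`, `table` (a
#'   [agreement_table()]) and `rater_ids`.
#' @export
combine_tracks <- function(a, b, config = combine_config()) {
  a <- normalize_track(a); b <- normalize_track(b)
  partition <- partition_timeline(a, b)
  resolved <- resolve_partition(partition, config)
  episodes <- flag_label_disagreements(a, b, merge_episodes(resolved))
  structure(
    list(trial_id = a$trial_id, config = config, partition = partition,
         resolved = resolved, episodes = episodes,
         table = tabulate_partition(partition),
         rater_ids = c(a$rater_id, b$rater_id)),
    class = "fog_combined"
  )
}

#' @export
print.fog_combined <- function(x, ...) {
  disc <- x$resolved[x$resolved$outcome == "discussion", , drop = FALSE]
  fog_ms <- sum((x$resolved$end_ms - x$resolved$begin_ms)[x$resolved$outcome == "FOG"])
  cat(sprintf("<fog_combined> trial '%s' (tolerance %s ms, correction '%s')\n",
              x$trial_id, format(x$config$tolerance_ms), x$config$correction))
  cat(sprintf("  %d combined FOG episode(s), %.3f s agreed FOG, %d segment(s) to discuss\n",
              nrow(x$episodes), fog_ms / 1000, nrow(disc)))
  invisible(x)
}

#' Percentage of observed time annotated as FOG
#'
#' Per-trial summary score: the share of the observation annotated as FOG,
#' either by one rater (`fog_track`) or in the combined agreed outcome
#' (`fog_combined`, where discussion segments count as not-FOG until
#' resolved by the third rater).
#'
#' @param x a `fog_track` or `fog_combined` object.
#' @return percentage in `[0, 100]`.
#' @export
percent_time_frozen <- function(x) {
  if (inherits(x, "fog_track")) {
    100 * sum(x$episodes$end_ms - x$episodes$begin_ms) / x$trial_duration_ms
  } else if (inherits(x, "fog_combined")) {
    fog <- x$resolved$outcome == "FOG"
    100 * sum((x$resolved$end_ms - x$resolved$begin_ms)[fog]) /
      x$partition$trial_duration_ms
  } else {
    stop("percent_time_frozen expects a fog_track or fog_combined object")
  }
}
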