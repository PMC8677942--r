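#' Subject-grouped stratified train/validation/test split
#'
#' Assigns whole subjects (all eyes, visits and recordings) to one of
#' train/validation/test, so no subject straddles sets, while balancing both
#' the waveform counts toward the requested fractions and the positive-label
#' proportion of each set toward the overall proportion. Assignment is a
#' seeded greedy pass over subjects (largest first, seeded random
#' tie-breaking); if after `max_tries` reseeded passes some set's positive
#' proportion deviates from the overall one by more than `tolerance`, an
#' error suggests relaxing it. Deterministic given `seed`.
#'
#' @param subject_ids Subject identifier per record (waveform).
#' @param labels Record labels (`ON_POS`/`ON_NEG`, logical, 0/1 or -1/1).
#' @param fractions Named or positional fractions for
#'   train/validation/test; must sum to 1. The defaults follow the study's
#'   258/161/172-waveform split.
#' @param seed Integer seed.
#' @param tolerance Allowed absolute deviation of each set's positive-label
#'   proportion from the overall proportion.
#' @param max_tries Reseeded greedy passes before giving up.
#' @return List of class `"SplitAssignment"` with `subject_to_set` (named
#'   character vector), `set` (per input record), `fractions`, `seed`,
#'   `tolerance`.
#' @export
groupedStratifiedSplit <- function(subject_ids, labels,
                                   fractions = c(train = 0.44,
                                                 validation = 0.27,
                                                 test = 0.29),
                                   seed = 1L, tolerance = 0.05,
                                   max_tries = 200L) {
  stopifnot(length(subject_ids) == length(labels))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  sets <- c("train", "validation", "test")
  fractions <- as.numeric(fractions)
  names(fractions) <- sets
  pos <- .asBinaryLabels(labels)
  subject_ids <- as.character(subject_ids)
  subs <- unique(subject_ids)
  n_rec <- as.numeric(table(factor(subject_ids, subs)))
  n_pos <- vapply(subs, function(s) sum(pos[subject_ids == s]), numeric(1))
  total <- length(subject_ids)
  p_all <- mean(pos)

  greedyPass <- function(try_seed) {
    ord <- .withSeed(try_seed, {
      jitter <- runif(length(subs))
      order(-n_rec, jitter)
    })
    count <- c(train = 0, validation = 0, test = 0)
    npos <- count
    assign <- setNames(character(length(subs)), subs)
    for (i in ord) {
      score <- vapply(sets, function(s) {
        cnt <- count; ps <- npos
        cnt[s] <- cnt[s] + n_rec[i]; ps[s] <- ps[s] + n_pos[i]
        # both penalties on the count scale, so a small set's imbalance does
        # not dominate the decision to open it
        size_pen <- sum(abs(cnt - fractions * total))
        lab_pen <- sum(abs(ps - p_all * cnt))
        (size_pen + 2 * lab_pen) / total
      }, numeric(1))
      s <- sets[which.min(score)]
      assign[subs[i]] <- s
      count[s] <- count[s] + n_rec[i]
      npos[s] <- npos[s] + n_pos[i]
    }
    list(assign = assign, count = count, npos = npos)
  }

  for (k in seq_len(max_tries)) {
    res <- greedyPass(seed + (k - 1L) * 1000L)
    prop <- res$npos / pmax(res$count, 1)
    if (all(res$count > 0) && all(abs(prop - p_all) <= tolerance + 1e-12)) {
      out <- list(subject_to_set = res$assign,
                  set = unname(res$assign[subject_ids]),
                  fractions = fractions, seed = as.integer(seed),
                  tolerance = tolerance)
      class(out) <- "SplitAssignment"
      return(out)
    }
  }
  stop(sprintf(paste("could not balance positive-label proportions within",
                     "tolerance %.3f after %d passes; relax 'tolerance'"),
               tolerance, max_tries))
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
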