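# PARE (degradome) cleavage profiling over precursor contexts.

#' Construct a PARE tag library
#'
#' @param sample_id sample identifier.
#' @param tags data.frame with `sequence` and `count` (unique sequences,
#'   positive counts); tags shorter than `min_len` nt are dropped with a
#'   warning (degradome tags are ~20-nt 5'-end signatures).
#' @param total_reads library scale used for TP10M normalization.
#' @param min_len minimum tag length retained (default 18).
#' @return list of class `pare_library`.
#' @export
pare_library <- function(sample_id, tags, total_reads = NULL, min_len = 18L) {
  stopifnot(is.data.frame(tags), all(c("sequence", "count") %in% names(tags)))
  if (anyDuplicated(tags$sequence)) stop("tags must be unique by sequence")
  if (any(tags$count <= 0)) stop("counts must be positive")
  short <- nchar(tags$sequence) < min_len
  if (any(short)) {
    warning(sum(short), " tag(s) shorter than ", min_len, " nt dropped")
    tags <- tags[!short, , drop = FALSE]
  }
  total <- total_reads %||% sum(tags$count)
  structure(list(sample_id = sample_id, tags = tags, total_reads = total),
            class = "pare_library")
}

#' TP10M normalization of tag abundances
#'
#' Transcripts per 10 million reads: `raw * 1e7 / total_reads`.
#'
#' @param lib a [pare_library()].
#' @return numeric vector of normalized abundances aligned with
#'   `lib$tags`.
#' @export
normalize_tp10m <- function(lib) {
  if (lib$total_reads <= 0) stop("total_reads must be positive")
  lib$tags$count * 1e7 / lib$total_reads
}

#' Per-position cleavage profile of sense-strand targets
#'
#' Tags are matched sense-strand over their full length (uncapped 5' RNA
#' ends are transcript fragments). The frequency at position `i`
#' (0-based) sums the TP10M abundances of all tags whose 5' end maps at
#' `i`, i.e. the cleavage between nucleotides `i - 1` and `i`. The
#' `unique` profile counts tags matching a single target; `max_possible`
#' adds tags that also match closely related homologs, in every matching
#' target.
#'
#' @param lib a [pare_library()].
#' @param targets named character vector, typically ~1 kb contexts with
#'   the precursor stem-loop at the centre.
#' @return data.frame of class `cleavage_profile` with columns `target`,
#'   `position`, `tp10m_unique`, `tp10m_max`; zero positions omitted.
#'   Attribute `target_lengths` holds the target lengths.
#' @export
pare_profile <- function(lib, targets) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  norm <- normalize_tp10m(lib)
  rows <- list()
  for (k in seq_len(nrow(lib$tags))) {
    tag <- lib$tags$sequence[k]
    hits <- lapply(targets, substring_starts, pattern = tag)
    nt <- sum(lengths(hits) > 0)
    if (nt == 0) next
    for (tid in names(hits)) {
      for (s in hits[[tid]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = tid, position = s,
          tp10m_unique = if (nt == 1L) norm[k] else 0,
          tp10m_max = norm[k], stringsAsFactors = FALSE)
      }
    }
  }
  prof <- if (length(rows)) {
    agg <- do.call(rbind, rows)
    u <- stats::aggregate(cbind(tp10m_unique, tp10m_max) ~ target + position,
                          agg, sum)
    u[order(u$target, u$position), , drop = FALSE]
  } else {
    data.frame(target = character(0), position = integer(0),
               tp10m_unique = numeric(0), tp10m_max = numeric(0))
  }
  rownames(prof) <- NULL
  attr(prof, "target_lengths") <- nchar(targets)
  class(prof) <- c("cleavage_profile", "data.frame")
  prof
}

#' Aggregate cleavage profiles across samples
#'
#' Positionwise sum over samples ("total cleavages"); also reports the
#' modal (most frequently cleaved) site per target, ties broken 5'-most.
#'
#' @param profiles list of `cleavage_profile` objects over the same
#'   target universe.
#' @return a `cleavage_profile` with attribute `modal_sites`: named
#'   integer vector of the modal cleavage position (by `tp10m_max`) per
#'   target.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all_rows <- do.call(rbind, lapply(profiles, function(p) {
    as.data.frame(p)[, c("target", "position", "tp10m_unique", "tp10m_max")]
  }))
  out <- if (nrow(all_rows)) {
    u <- stats::aggregate(cbind(tp10m_unique, tp10m_max) ~ target + position,
                          all_rows, sum)
    u[order(u$target, u$position), , drop = FALSE]
  } else all_rows
  rownames(out) <- NULL
  modal <- vapply(split(out, out$target), function(g) {
    g$position[order(-g$tp10m_max, g$position)][1]
  }, numeric(1))
  attr(out, "target_lengths") <- attr(profiles[[1]], "target_lengths")
  attr(out, "modal_sites") <- modal
  class(out) <- c("cleavage_profile", "data.frame")
  out
}

#' Restrict a profile to a sub-interval of one target
#'
#' Returns the profile rows falling in `interval` with positions shifted
#' to interval-local coordinates (used to read precursor-local cleavage
#' off a whole-context profile).
#'
#' @param profile a `cleavage_profile`.
#' @param target target id.
#' @param interval 0-based half-open interval on the target.
#' @return data.frame with local `position` and the tp10m columns.
#' @export
profile_window <- function(profile, target, interval) {
  g <- profile[profile$target == target &
                 profile$position >= interval[1] &
                 profile$position < interval[2], , drop = FALSE]
  g$position <- g$position - interval[1]
  rownames(g) <- NULL
  as.data.frame(g)
}
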