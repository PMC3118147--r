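# Small-RNA mapping, normalization and nine-partition quantification.

#' Construct a small-RNA library
#'
#' @param sample_id sample identifier.
#' @param records data.frame with `sequence` and `count` (unique
#'   sequences, positive counts).
#' @param total_reads library sequencing scale; defaults to the record
#'   sum, may exceed it (unmapped portion of the library).
#' @param pre_normalized logical; `TRUE` when counts are already on a
#'   common scale, in which case [normalize_libraries()] applies factor 1.
#' @return list of class `srna_library`.
#' @export
srna_library <- function(sample_id, records, total_reads = NULL,
                         pre_normalized = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("sequence", "count") %in% names(records)))
  if (anyDuplicated(records$sequence)) stop("records must be unique by sequence")
  if (any(records$count <= 0)) stop("counts must be positive")
  total <- total_reads %||% sum(records$count)
  if (total < sum(records$count) - 1e-9) {
    stop("total_reads smaller than the sum of record counts")
  }
  structure(list(sample_id = sample_id, records = records,
                 total_reads = total, pre_normalized = pre_normalized),
            class = "srna_library")
}

#' Map reads to precursors (perfect match only)
#'
#' Every exact substring occurrence of each distinct read in each
#' precursor is reported. `multiplicity` counts the distinct precursors
#' a read matches (`shared` is `multiplicity > 1`); a read occurring at
#' several positions of one precursor is placed at each with its
#' abundance split equally (`weight`).
#'
#' @param lib an [srna_library()].
#' @param precursors named character vector of precursor sequences.
#' @return data.frame with columns `sequence`, `count`, `precursor`,
#'   `start`, `end`, `multiplicity`, `shared`, `weight`.
#' @export
map_reads <- function(lib, precursors) {
  stopifnot(length(precursors) > 0, !is.null(names(precursors)))
  out <- list()
  for (k in seq_len(nrow(lib$records))) {
    read <- lib$records$sequence[k]
    hits <- list()
    for (pid in names(precursors)) {
      starts <- substring_starts(precursors[[pid]], read)
      if (length(starts)) hits[[pid]] <- starts
    }
    if (!length(hits)) next
    mult <- length(hits)
    for (pid in names(hits)) {
      starts <- hits[[pid]]
      out[[length(out) + 1L]] <- data.frame(
        sequence = read, count = lib$records$count[k], precursor = pid,
        start = starts, end = starts + nchar(read),
        multiplicity = mult, shared = mult > 1L,
        weight = 1 / length(starts), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), count = numeric(0),
                      precursor = character(0), start = integer(0),
                      end = integer(0), multiplicity = integer(0),
                      shared = logical(0), weight = numeric(0)))
  }
  do.call(rbind, out)
}

# all 0-based start positions of an exact (possibly overlapping) match
substring_starts <- function(text, pattern) {
  res <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (i < 0) break
    res <- c(res, from + i - 2L)  # 0-based
    from <- from + i              # allow overlaps
  }
  res
}

#' Mean-total normalization factors across samples
#'
#' Abundances are scaled to the average sequencing scale of the batch:
#' `factor_s = mean(total_reads) / total_reads_s`. Libraries flagged
#' `pre_normalized` receive factor 1.
#'
#' @param libs list of [srna_library()] objects.
#' @return named numeric vector of per-sample scale factors.
#' @export
normalize_libraries <- function(libs) {
  stopifnot(length(libs) >= 1)
  totals <- vapply(libs, `[[`, numeric(1), "total_reads")
  if (any(totals <= 0)) stop("total_reads must be positive")
  pre <- vapply(libs, `[[`, logical(1), "pre_normalized")
  f <- mean(totals) / totals
  f[pre] <- 1
  names(f) <- vapply(libs, `[[`, character(1), "sample_id")
  f
}

#' Quantification parameters
#'
#' @param overlap_fraction minimum fraction of a read's nucleotides that
#'   must overlap a partition for assignment (default 0.8; for a 21-nt
#'   read this is 17 nt, `ceiling(0.8 * 21)`).
#' @param ratio_floor normalized-abundance floor used by the ratio
#'   conventions (default 1).
#' @return list of class `quant_params`.
#' @export
quant_params <- function(overlap_fraction = 0.8, ratio_floor = 1.0) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  structure(list(overlap_fraction = overlap_fraction,
                 ratio_floor = ratio_floor), class = "quant_params")
}

#' Assign a read placement to a partition (or leak)
#'
#' The placement goes to the partition maximizing the overlap, provided
#' the overlap covers at least `overlap_fraction` of the read; otherwise
#' it is leak (read inconsistent with the phased processing register).
#' With disjoint partitions and a fraction above 0.5 at most one
#' partition can qualify.
#'
#' @param interval 0-based half-open read interval on the precursor.
#' @param scheme a `partition_scheme`.
#' @param params a [quant_params()].
#' @return partition name, or `"leak"`.
#' @export
assign_partition <- function(interval, scheme, params = quant_params()) {
  L <- interval[2] - interval[1]
  ov <- pmax(0, pmin(interval[2], scheme$end) - pmax(interval[1], scheme$start))
  best <- which.max(ov)
  if (ov[best] / L >= params$overlap_fraction) scheme$name[best] else "leak"
}

#' Quantify partitioned expression of precursors in each sample
#'
#' For every precursor with a partition scheme, sums normalized
#' abundances per partition: `unique` uses only reads matching a single
#' precursor; `max_possible` additionally counts reads shared with
#' paralogs at full weight in every matching precursor. Reads below the
#' overlap threshold accumulate in the `leak` row. Optional `groups`
#' (named lists of precursor ids) are quantified as pooled
#' pseudo-precursors in which a shared read is counted once per group.
#'
#' @param libs list of [srna_library()] objects.
#' @param precursors named character vector.
#' @param schemes named list of `partition_scheme` objects (names =
#'   precursor ids).
#' @param params a [quant_params()].
#' @param groups optional named list of character vectors of member ids.
#' @return data.frame with columns `sample`, `precursor`, `partition`,
#'   `unique`, `max_possible` (normalized units); `partition` includes
#'   `"leak"`.
#' @export
quantify <- function(libs, precursors, schemes, params = quant_params(),
                     groups = NULL) {
  factors <- normalize_libraries(libs)
  part_names <- c("sp1", "miR*", "sp2", "ACR5", "sp3", "ACR3", "sp4", "miR",
                  "sp5", "leak")
  out <- list()
  for (lib in libs) {
    f <- factors[[lib$sample_id]]
    pl <- map_reads(lib, precursors)
    if (nrow(pl)) {
      pl$norm <- pl$count * f * pl$weight
      pl$partition <- vapply(seq_len(nrow(pl)), function(i) {
        sch <- schemes[[pl$precursor[i]]]
        if (is.null(sch)) return(NA_character_)
        assign_partition(c(pl$start[i], pl$end[i]), sch, params)
      }, character(1))
      pl <- pl[!is.na(pl$partition), , drop = FALSE]
    } else {
      pl$norm <- numeric(0)
      pl$partition <- character(0)
    }
    for (pid in names(schemes)) {
      sub <- pl[pl$precursor == pid, , drop = FALSE]
      for (part in part_names) {
        rows <- sub[sub$partition == part, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          sample = lib$sample_id, precursor = pid, partition = part,
          unique = sum(rows$norm[!rows$shared]),
          max_possible = sum(rows$norm), stringsAsFactors = FALSE)
      }
    }
    if (!is.null(groups)) {
      for (gname in names(groups)) {
        members <- groups[[gname]]
        sub <- pl[pl$precursor %in% members, , drop = FALSE]
        for (part in part_names) {
          rows <- sub[sub$partition == part, , drop = FALSE]
          # a read shared among group members is counted once per group:
          # collapse to distinct (sequence, partition) with the read's
          # normalized abundance
          if (nrow(rows)) {
            agg <- rows[!duplicated(rows$sequence), , drop = FALSE]
            val <- sum(agg$count * f)
          } else val <- 0
          out[[length(out) + 1L]] <- data.frame(
            sample = lib$sample_id, precursor = gname, partition = part,
            unique = NA_real_, max_possible = val, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Mutant-to-wild-type expression ratio per partition
#'
#' Replicates are averaged first; the ratio uses the `max_possible`
#' abundances. If both the mutant and wild-type means fall below
#' `ratio_floor` the ratio is reported as 1 and flagged `absent`
#' (absence or near absence in both genotypes). If only the denominator
#' is below the floor it is replaced by the floor and the value flagged
#' `floored`.
#'
#' @param expr_mut,expr_wt quantification tables from [quantify()]; the
#'   mutant/wild-type tables may each contain several replicate samples.
#' @param params a [quant_params()].
#' @return data.frame with `precursor`, `partition`, `mut`, `wt`,
#'   `ratio`, `flag` (`""`, `"absent"` or `"floored"`).
#' @export
ratio_mut_wt <- function(expr_mut, expr_wt, params = quant_params()) {
  mean_tab <- function(e) {
    stats::aggregate(max_possible ~ precursor + partition, e, mean)
  }
  m <- mean_tab(expr_mut); w <- mean_tab(expr_wt)
  tab <- merge(m, w, by = c("precursor", "partition"),
               suffixes = c("_mut", "_wt"), all = TRUE)
  tab$max_possible_mut[is.na(tab$max_possible_mut)] <- 0
  tab$max_possible_wt[is.na(tab$max_possible_wt)] <- 0
  fl <- params$ratio_floor
  res <- lapply(seq_len(nrow(tab)), function(i) {
    mu <- tab$max_possible_mut[i]; wt <- tab$max_possible_wt[i]
    if (mu < fl && wt < fl) {
      c(ratio = 1, flag = "absent")
    } else if (wt < fl) {
      c(ratio = mu / fl, flag = "floored")
    } else {
      c(ratio = mu / wt, flag = "")
    }
  })
  data.frame(precursor = tab$precursor, partition = tab$partition,
             mut = tab$max_possible_mut, wt = tab$max_possible_wt,
             ratio = as.numeric(vapply(res, `[[`, character(1), "ratio")),
             flag = vapply(res, `[[`, character(1), "flag"),
             stringsAsFactors = FALSE)
}

#' Mutant-to-wild-type ratio of total abundance per read-length bin
#'
#' The overall size-class enrichment (e.g. 20-21 nt versus 24 nt) against
#' which per-partition up-regulation is judged. Same floor conventions as
#' [ratio_mut_wt()].
#'
#' @param libs_mut,libs_wt lists of [srna_library()] objects (replicates).
#' @param bins named list of integer vectors of read lengths, e.g.
#'   `list("20-21" = 20:21, "24" = 24)`; bins must be disjoint.
#' @param params a [quant_params()].
#' @return data.frame with `bin`, `mut`, `wt`, `ratio`, `flag`.
#' @export
length_class_ratio <- function(libs_mut, libs_wt, bins, params = quant_params()) {
  if (anyDuplicated(unlist(bins))) stop("length bins must be disjoint")
  side_mean <- function(libs) {
    f <- normalize_libraries(libs)
    per_sample <- vapply(libs, function(lib) {
      len <- nchar(lib$records$sequence)
      vapply(bins, function(b) {
        sum(lib$records$count[len %in% b]) * f[[lib$sample_id]]
      }, numeric(1))
    }, numeric(length(bins)))
    if (is.null(dim(per_sample))) per_sample <- matrix(per_sample, nrow = 1)
    rowMeans(per_sample)
  }
  mu <- side_mean(libs_mut); wt <- side_mean(libs_wt)
  fl <- params$ratio_floor
  ratio <- numeric(length(bins)); flag <- character(length(bins))
  for (i in seq_along(bins)) {
    if (mu[i] < fl && wt[i] < fl) { ratio[i] <- 1; flag[i] <- "absent" }
    else if (wt[i] < fl) { ratio[i] <- mu[i] / fl; flag[i] <- "floored" }
    else { ratio[i] <- mu[i] / wt[i]; flag[i] <- "" }
  }
  data.frame(bin = names(bins), mut = mu, wt = wt, ratio = ratio,
             flag = flag, stringsAsFactors = FALSE)
}
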