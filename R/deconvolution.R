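#' Simulate sequencing reads from sorted hit beads
#'
#' One read per hit bead: the member's concatenated encoding tag with
#' i.i.d. per-base substitution errors at `error_rate` (each error replaces
#' the base with one of the three other bases, uniformly).
#'
#' @param sort a `del_sort_result` whose `hit_beads` carry member indices.
#' @param catalog the `del_catalog` screened.
#' @param error_rate per-base substitution probability, in \[0, 0.2).
#' @param seed integer seed.
#' @return data.frame of class `del_tag_reads`: read_id, sequence.
#' @export
reads_from_hits <- function(sort, catalog, error_rate = 0.005, seed) {
  stopifnot(inherits(sort, "del_sort_result"),
            inherits(catalog, "del_catalog"))
  if (missing(seed)) stop("reads_from_hits() requires an explicit seed")
  if (error_rate < 0 || error_rate >= 0.2) {
    stop("error_rate must be in [0, 0.2)")
  }
  set.seed(as.integer(seed))
  seqs <- catalog$members$tag[sort$hit_beads$member]
  n <- length(seqs)
  if (n > 0 && error_rate > 0) {
    L <- nchar(seqs[1])
    mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n,
                  byrow = TRUE)
    err <- matrix(stats::runif(n * L) < error_rate, n, L)
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- mat[err]
      # substitute with one of the three other bases
      sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      mat[err] <- sub
      seqs <- apply(mat, 1L, paste, collapse = "")
    }
  }
  out <- data.frame(read_id = sprintf("r%06d", seq_len(n)),
                    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("del_tag_reads", "data.frame")
  out
}

#' Write / read tag reads as FASTQ
#'
#' Simulated reads carry a uniform placeholder quality ("I" = Q40).
#'
#' @param reads a `del_tag_reads` data.frame (read_id, sequence).
#' @param path FASTQ file path (plain text, uncompressed).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in%
                                        names(reads)))
  dss <- Biostrings::DNAStringSet(reads$sequence)
  names(dss) <- reads$read_id
  qual <- Biostrings::BStringSet(vapply(
    nchar(reads$sequence), function(l) strrep("I", l), ""))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- data.frame(read_id = names(dss), sequence = as.character(dss),
                    stringsAsFactors = FALSE)
  class(out) <- c("del_tag_reads", "data.frame")
  out
}

# Hamming match of read segments against a cycle's tag set.
# N is treated as a wildcard (contributes no mismatch). Returns the index
# of the unique tag within max_dist, 0 for no match, -1 for ambiguous.
.match_segments <- function(segments, tags, max_dist = 1L) {
  res <- match(segments, tags)           # exact matches, vectorized
  res[is.na(res)] <- NA_integer_
  todo <- which(is.na(res))
  if (!length(todo)) return(res)
  L <- nchar(tags[1])
  tag_mat <- matrix(unlist(strsplit(tags, "", fixed = TRUE)),
                    nrow = length(tags), byrow = TRUE)
  useg <- unique(segments[todo])
  umatch <- vapply(useg, function(s) {
    if (nchar(s) != L) return(0L)
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    cmp <- tag_mat != matrix(sv, nrow(tag_mat), L, byrow = TRUE)
    cmp[, sv == "N"] <- FALSE
    d <- rowSums(cmp)
    hit <- which(d <= max_dist)
    if (length(hit) == 1L) hit else if (length(hit) > 1L) -1L else 0L
  }, integer(1))
  res[todo] <- umatch[match(segments[todo], useg)]
  res
}

#' Decode tag reads to library members
#'
#' Each read is split into its cycle-1 and cycle-2 tag segments. A segment
#' is matched exactly against the cycle's tag set, or failing that to the
#' unique tag within Hamming distance 1 (the generator guarantees pairwise
#' tag distance >= 3, so a single substitution is correctable). N bases are
#' wildcards; a read whose segment matches more than one tag (e.g. heavily
#' N-masked) is discarded as ambiguous, and a segment matching no tag
#' discards the read as unmatched. Reads of the wrong length are discarded.
#'
#' @param reads a `del_tag_reads` data.frame (or character vector of
#'   sequences, or a FASTQ path).
#' @param catalog the `del_catalog`; its tag sets must be unambiguous.
#' @return list of class `del_decode_result`: `counts` (data.frame
#'   member_id, member, k for members with k >= 1), `n_decoded`,
#'   `discarded` (data.frame read_id, reason).
#' @export
decode_reads <- function(reads, catalog) {
  stopifnot(inherits(catalog, "del_catalog"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("r%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  # a tag set in which two tags lie within distance 2 cannot support
  # 1-error correction: reject at load
  for (cyc in list(catalog$aa$tag, catalog$ca$tag)) {
    if (length(cyc) > 1L) {
      tm <- matrix(unlist(strsplit(cyc, "", fixed = TRUE)),
                   nrow = length(cyc), byrow = TRUE)
      for (i in seq_len(nrow(tm) - 1L)) {
        d <- rowSums(tm[-seq_len(i), , drop = FALSE] !=
                       matrix(tm[i, ], nrow(tm) - i, ncol(tm), byrow = TRUE))
        if (any(d < 3)) stop("catalog tags are ambiguous (pairwise ",
                             "Hamming distance < 3) within a cycle")
      }
    }
  }
  la <- catalog$aa_tag_len; lc <- catalog$ca_tag_len
  seqs <- toupper(reads$sequence)
  good_len <- nchar(seqs) == la + lc
  aa_m <- rep(0L, length(seqs)); ca_m <- rep(0L, length(seqs))
  if (any(good_len)) {
    aa_m[good_len] <- .match_segments(substr(seqs[good_len], 1L, la),
                                      catalog$aa$tag)
    ca_m[good_len] <- .match_segments(substr(seqs[good_len], la + 1L,
                                             la + lc), catalog$ca$tag)
  }
  reason <- rep(NA_character_, length(seqs))
  reason[!good_len] <- "bad_length"
  reason[good_len & (aa_m == -1L | ca_m == -1L)] <- "ambiguous"
  reason[good_len & is.na(reason) & (aa_m == 0L | ca_m == 0L)] <- "unmatched"
  ok <- is.na(reason)
  member <- (aa_m[ok] - 1L) * catalog$ca_count + ca_m[ok]
  tab <- table(member)
  midx <- as.integer(names(tab))
  counts <- data.frame(member_id = catalog$members$member_id[midx],
                       member = midx, k = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$member), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(
    counts = counts, n_decoded = sum(ok),
    discarded = data.frame(read_id = reads$read_id[!ok],
                           reason = reason[!ok], stringsAsFactors = FALSE)
  ), class = "del_decode_result")
}

#' Per-member k classes and per-building-block cumulative k
#'
#' The k class of a library member is its replicate count — the number of
#' independent hit beads decoding to it. The cumulative k of a building
#' block sums the k of every member containing that block. Members with
#' k >= 2 are flagged replicate-supported.
#'
#' @param counts a `del_decode_result`, or a data.frame(member_id, k).
#' @param catalog the `del_catalog`.
#' @param screen_label label for this screen (e.g. "uv100").
#' @return object of class `del_kclass_table`: `members` (member_id, aa_id,
#'   ca_id, k, replicate_supported), `bb` (bb_id, cycle, cum_k),
#'   `screen_label`, `n_decoded`.
#' @export
k_class_table <- function(counts, catalog, screen_label = "screen") {
  stopifnot(inherits(catalog, "del_catalog"))
  if (inherits(counts, "del_decode_result")) counts <- counts$counts
  stopifnot(is.data.frame(counts), all(c("member_id", "k") %in%
                                         names(counts)))
  midx <- match(counts$member_id, catalog$members$member_id)
  if (anyNA(midx)) stop("counts reference members absent from the catalog")
  members <- data.frame(
    member_id = counts$member_id,
    aa_id = catalog$members$aa_id[midx],
    ca_id = catalog$members$ca_id[midx],
    k = as.integer(counts$k),
    replicate_supported = counts$k >= 2L,
    stringsAsFactors = FALSE
  )
  cum_aa <- tapply(members$k, members$aa_id, sum)
  cum_ca <- tapply(members$k, members$ca_id, sum)
  bb <- rbind(
    data.frame(bb_id = names(cum_aa), cycle = 1L,
               cum_k = as.integer(cum_aa), stringsAsFactors = FALSE),
    data.frame(bb_id = names(cum_ca), cycle = 2L,
               cum_k = as.integer(cum_ca), stringsAsFactors = FALSE)
  )
  bb <- bb[order(-bb$cum_k, bb$bb_id), , drop = FALSE]
  rownames(bb) <- NULL
  structure(list(members = members, bb = bb, screen_label = screen_label,
                 n_decoded = sum(members$k),
                 catalog_signature = .catalog_signature(catalog)),
            class = "del_kclass_table")
}

.catalog_signature <- function(catalog) {
  paste(catalog$aa_count, catalog$ca_count,
        catalog$aa$tag[1], catalog$ca$tag[1], sep = "|")
}

#' @export
print.del_kclass_table <- function(x, ...) {
  cat(sprintf("k-class table '%s': %d decoded hit beads, %d members, top BB %s (cum k = %d)\n",
              x$screen_label, x$n_decoded, nrow(x$members),
              x$bb$bb_id[1], x$bb$cum_k[1]))
  invisible(x)
}

#' Dose-conforming comparison of high- and low-UV screens
#'
#' Tiers every building block observed in either screen by its cumulative k
#' at the high and low UV dose:
#' \itemize{
#'   \item `high_priority` — cumulative k >= `min_k` at both doses
#'     (enrichment conforms with dose);
#'   \item `dose_limited` — cumulative k >= `min_k` at the high dose only
#'     (candidate too weak to register at the reduced released dose);
#'   \item `noise` — max cumulative k <= `noise_k` at both doses
#'     (bordering the experimental noise level);
#'   \item `unobserved` — anything else (not enriched beyond noise at the
#'     high dose).
#' }
#' Also reports disynthon (member-pair) level k for pairs with combined
#' k >= 2.
#'
#' @param high,low `del_kclass_table`s from the high- and low-UV screens of
#'   the same catalog.
#' @param min_k enrichment threshold on cumulative k (default 4).
#' @param noise_k noise ceiling on cumulative k (default 3).
#' @return object of class `del_dose_report`: `bb` (bb_id, cycle, k_high,
#'   k_low, tier; sorted by k_high + k_low descending, ties by bb_id),
#'   `disynthons` (member_id, aa_id, ca_id, k_high, k_low), `min_k`,
#'   `noise_k`, `labels`.
#' @export
dose_compare <- function(high, low, min_k = 4L, noise_k = 3L) {
  stopifnot(inherits(high, "del_kclass_table"),
            inherits(low, "del_kclass_table"))
  if (!identical(high$catalog_signature, low$catalog_signature)) {
    stop("high and low screens reference different catalogs")
  }
  ids <- unique(rbind(high$bb[c("bb_id", "cycle")],
                      low$bb[c("bb_id", "cycle")]))
  k_high <- high$bb$cum_k[match(ids$bb_id, high$bb$bb_id)]
  k_low <- low$bb$cum_k[match(ids$bb_id, low$bb$bb_id)]
  k_high[is.na(k_high)] <- 0L
  k_low[is.na(k_low)] <- 0L
  tier <- ifelse(
    k_high >= min_k & k_low >= min_k, "high_priority",
    ifelse(k_high >= min_k, "dose_limited",
           ifelse(pmax(k_high, k_low) <= noise_k, "noise", "unobserved")))
  bb <- data.frame(bb_id = ids$bb_id, cycle = ids$cycle,
                   k_high = k_high, k_low = k_low, tier = tier,
                   stringsAsFactors = FALSE)
  bb <- bb[order(-(bb$k_high + bb$k_low), bb$bb_id), , drop = FALSE]
  rownames(bb) <- NULL

  dm <- merge(high$members[c("member_id", "aa_id", "ca_id", "k")],
              low$members[c("member_id", "k")],
              by = "member_id", all = TRUE, suffixes = c("_high", "_low"))
  dm$k_high[is.na(dm$k_high)] <- 0L
  dm$k_low[is.na(dm$k_low)] <- 0L
  miss <- is.na(dm$aa_id)
  if (any(miss)) {
    li <- match(dm$member_id[miss], low$members$member_id)
    dm$aa_id[miss] <- low$members$aa_id[li]
    dm$ca_id[miss] <- low$members$ca_id[li]
  }
  dm <- dm[dm$k_high + dm$k_low >= 2L,
           c("member_id", "aa_id", "ca_id", "k_high", "k_low")]
  dm <- dm[order(-(dm$k_high + dm$k_low), dm$member_id), , drop = FALSE]
  rownames(dm) <- NULL

  structure(list(bb = bb, disynthons = dm, min_k = min_k, noise_k = noise_k,
                 labels = c(high = high$screen_label,
                            low = low$screen_label)),
            class = "del_dose_report")
}

#' @export
print.del_dose_report <- function(x, ...) {
  tt <- table(factor(x$bb$tier, levels = c("high_priority", "dose_limited",
                                           "noise", "unobserved")))
  cat(sprintf("Dose comparison (%s vs %s): %d BBs observed\n",
              x$labels[["high"]], x$labels[["low"]], nrow(x$bb)))
  cat(sprintf("  high_priority %d | dose_limited %d | noise %d | unobserved %d\n",
              tt[1], tt[2], tt[3], tt[4]))
  invisible(x)
}

#' Write a dose-comparison report as TSV and JSON
#'
#' @param report a `del_dose_report`.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @export
write_dose_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "del_dose_report"))
  if (!is.null(tsv_path)) {
    utils::write.table(report$bb, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(bb = report$bb, disynthons = report$disynthons,
           min_k = report$min_k, noise_k = report$noise_k,
           labels = as.list(report$labels)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
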