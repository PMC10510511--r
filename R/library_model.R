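#' Generate a set of DNA encoding tags with minimum pairwise Hamming distance
#'
#' Encoding tags identify building blocks within a synthesis cycle. Tags are
#' drawn uniformly at random over \{A,C,G,T\} and accepted greedily so that
#' every pair within the set differs at `min_dist` or more positions. With
#' the default distance of 3, a single sequencing substitution can be
#' corrected unambiguously during decoding.
#'
#' @param n number of tags to generate.
#' @param length tag length in nucleotides (default 12).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed integer seed; the tag set is reproducible given the seed.
#' @return character vector of `n` tags.
#' @export
generate_tags <- function(n, length = 12L, min_dist = 3L, seed) {
  stopifnot(n >= 1, length >= min_dist, min_dist >= 1)
  if (missing(seed)) stop("generate_tags() requires an explicit seed")
  if (4^length < n) stop("tag space too small for ", n, " tags")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  # accepted tags kept as an integer matrix (rows = tags) for fast
  # Hamming screening of each candidate
  acc <- matrix(integer(0), nrow = 0, ncol = length)
  tries <- 0L
  while (nrow(acc) < n) {
    cand <- sample.int(4L, length, replace = TRUE)
    ok <- TRUE
    if (nrow(acc) > 0) {
      mism <- rowSums(acc != matrix(cand, nrow(acc), length, byrow = TRUE))
      ok <- all(mism >= min_dist)
    }
    if (ok) acc <- rbind(acc, cand)
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("could not place ", n, " tags at min_dist ", min_dist,
           " within the rejection budget; increase tag length")
    }
  }
  apply(acc, 1L, function(r) paste(bases[r], collapse = ""))
}

#' Construct a building-block table for one synthesis cycle
#'
#' @param bb_id character vector of unique building-block identifiers.
#' @param cycle 1 (amino acid) or 2 (carboxylic acid).
#' @param tag DNA tags, one per block, equal length, unique within the cycle.
#' @param mw,clogp,hbd,hba,rotb optional per-block property vectors
#'   (molecular weight in Da, cLogP, H-bond donors/acceptors, rotatable
#'   bonds). May be omitted (`NA`) when properties are attached downstream.
#' @return data.frame with class `del_bb_set`.
#' @export
building_blocks <- function(bb_id, cycle, tag,
                            mw = NA_real_, clogp = NA_real_,
                            hbd = NA_real_, hba = NA_real_,
                            rotb = NA_real_) {
  cycle <- as.integer(cycle)
  stopifnot(length(cycle) == 1L, cycle %in% c(1L, 2L))
  n <- length(bb_id)
  if (n == 0L) stop("building-block set must be non-empty")
  if (anyDuplicated(bb_id)) stop("duplicate bb_id within cycle ", cycle)
  .validate_tags(tag, cycle)
  df <- data.frame(
    bb_id = as.character(bb_id), cycle = cycle, tag = as.character(tag),
    mw = rep_len(as.numeric(mw), n), clogp = rep_len(as.numeric(clogp), n),
    hbd = rep_len(as.numeric(hbd), n), hba = rep_len(as.numeric(hba), n),
    rotb = rep_len(as.numeric(rotb), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(df$mw) & df$mw <= 0)) stop("mw must be > 0")
  cnt <- c("hbd", "hba", "rotb")
  if (any(!is.na(unlist(df[cnt])) & unlist(df[cnt]) < 0)) {
    stop("property counts must be >= 0")
  }
  class(df) <- c("del_bb_set", "data.frame")
  df
}

.validate_tags <- function(tag, cycle) {
  if (any(is.na(tag)) || length(tag) == 0L) stop("missing tags")
  if (length(unique(nchar(tag))) != 1L) {
    stop("tags must share one length within cycle ", cycle)
  }
  if (any(grepl("[^ACGT]", tag))) {
    stop("tag alphabet must be A/C/G/T (cycle ", cycle, ")")
  }
  dup <- tag[duplicated(tag)]
  if (length(dup)) {
    stop("duplicate tag(s) within cycle ", cycle, ": ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(TRUE)
}

#' Enumerate a two-cycle combinatorial library
#'
#' Forms the full Cartesian product of cycle-1 amino acids and cycle-2
#' carboxylic acids, in stable amino-acid-major order, concatenating the
#' cycle tags (AA tag first) into the member's encoding tag. Member
#' properties are an additive fragment approximation of the photocleaved
#' primary amide: MW sums minus one water (18.02 Da, amide condensation),
#' cLogP and counts sum.
#'
#' @param aa_set cycle-1 `del_bb_set` (amino acids).
#' @param ca_set cycle-2 `del_bb_set` (carboxylic acids).
#' @return object of class `del_catalog`: list with `aa`, `ca`, and a
#'   `members` data.frame (member_id, aa_id, ca_id, tag, properties).
#' @examples
#' aa <- building_blocks(c("a1", "a2"), 1, c("ACGTACGTACGT", "TGCATGCATGCA"),
#'                       mw = 200, clogp = 1, hbd = 1, hba = 2, rotb = 2)
#' ca <- building_blocks("c1", 2, "GGGGCCCCAAAA",
#'                       mw = 150, clogp = 0.5, hbd = 0, hba = 1, rotb = 1)
#' cat55 <- enumerate_library(aa, ca)
#' nrow(cat55$members)  # 2
#' @export
enumerate_library <- function(aa_set, ca_set) {
  stopifnot(inherits(aa_set, "del_bb_set"), inherits(ca_set, "del_bb_set"))
  if (aa_set$cycle[1] != 1L || ca_set$cycle[1] != 2L) {
    stop("aa_set must be cycle 1 and ca_set cycle 2")
  }
  .validate_tags(aa_set$tag, 1L)
  .validate_tags(ca_set$tag, 2L)
  n_aa <- nrow(aa_set); n_ca <- nrow(ca_set)
  aa_idx <- rep(seq_len(n_aa), each = n_ca)
  ca_idx <- rep(seq_len(n_ca), times = n_aa)
  n <- n_aa * n_ca
  members <- data.frame(
    member_id = sprintf("m%06d", seq_len(n)),
    aa_id = aa_set$bb_id[aa_idx],
    ca_id = ca_set$bb_id[ca_idx],
    tag = paste0(aa_set$tag[aa_idx], ca_set$tag[ca_idx]),
    mw = aa_set$mw[aa_idx] + ca_set$mw[ca_idx] - 18.02,
    clogp = aa_set$clogp[aa_idx] + ca_set$clogp[ca_idx],
    hbd = aa_set$hbd[aa_idx] + ca_set$hbd[ca_idx],
    hba = aa_set$hba[aa_idx] + ca_set$hba[ca_idx],
    rotb = aa_set$rotb[aa_idx] + ca_set$rotb[ca_idx],
    stringsAsFactors = FALSE
  )
  out <- list(
    aa = aa_set, ca = ca_set, members = members,
    aa_count = n_aa, ca_count = n_ca,
    aa_tag_len = nchar(aa_set$tag[1]), ca_tag_len = nchar(ca_set$tag[1])
  )
  class(out) <- "del_catalog"
  out
}

#' @export
print.del_catalog <- function(x, ...) {
  cat(sprintf("DEL catalog: %d members (%d AA x %d COOH), tags %d+%d nt\n",
              nrow(x$members), x$aa_count, x$ca_count,
              x$aa_tag_len, x$ca_tag_len))
  invisible(x)
}

#' Decode a concatenated encoding tag back to its building blocks
#'
#' Exact inverse of the concatenation performed by [enumerate_library()];
#' used to assert that encoding is injective. For error-tolerant decoding of
#' sequencing reads see [decode_reads()].
#'
#' @param tags character vector of concatenated tags.
#' @param catalog a `del_catalog`.
#' @return data.frame(aa_id, ca_id); NA where a segment has no exact match.
#' @export
decode_tag <- function(tags, catalog) {
  stopifnot(inherits(catalog, "del_catalog"))
  aa_seg <- substr(tags, 1L, catalog$aa_tag_len)
  ca_seg <- substr(tags, catalog$aa_tag_len + 1L,
                   catalog$aa_tag_len + catalog$ca_tag_len)
  data.frame(
    aa_id = catalog$aa$bb_id[match(aa_seg, catalog$aa$tag)],
    ca_id = catalog$ca$bb_id[match(ca_seg, catalog$ca$tag)],
    stringsAsFactors = FALSE
  )
}

#' Profile library member properties against fragment- and drug-likeness
#'
#' Computes per-property histograms and the fractions of members passing the
#' rule-of-5 drug-like thresholds (MW < 500 Da, cLogP < 5) and rule-of-3
#' fragment-like thresholds (MW < 300, cLogP < 3, HBD <= 3, HBA <= 3,
#' rotatable bonds <= 3).
#'
#' @param catalog a `del_catalog` whose members all carry properties.
#' @return list of class `del_property_profile` with elements `fractions`
#'   (named numeric, all in \[0,1\]), `histograms` (list of `hist` objects),
#'   and `n`.
#' @export
profile_properties <- function(catalog) {
  stopifnot(inherits(catalog, "del_catalog"))
  m <- catalog$members
  props <- c("mw", "clogp", "hbd", "hba", "rotb")
  miss <- !stats::complete.cases(m[props])
  if (any(miss)) {
    stop("members missing properties: ",
         paste(utils::head(m$member_id[miss], 10L), collapse = ", "),
         if (sum(miss) > 10L) sprintf(" (and %d more)", sum(miss) - 10L))
  }
  n <- nrow(m)
  fractions <- c(
    ro5_mw = mean(m$mw < 500),
    ro5_clogp = mean(m$clogp < 5),
    ro5_all = mean(m$mw < 500 & m$clogp < 5),
    ro3_mw = mean(m$mw < 300),
    ro3_clogp = mean(m$clogp < 3),
    ro3_hbd = mean(m$hbd <= 3),
    ro3_hba = mean(m$hba <= 3),
    ro3_rotb = mean(m$rotb <= 3),
    ro3_all = mean(m$mw < 300 & m$clogp < 3 & m$hbd <= 3 &
                     m$hba <= 3 & m$rotb <= 3)
  )
  histograms <- lapply(props, function(p) graphics::hist(m[[p]], plot = FALSE))
  names(histograms) <- props
  structure(list(fractions = fractions, histograms = histograms, n = n),
            class = "del_property_profile")
}

#' @export
print.del_property_profile <- function(x, ...) {
  cat(sprintf("Property profile over %d members\n", x$n))
  cat(sprintf("  MW < 500 Da : %5.1f%%   cLogP < 5 : %5.1f%%\n",
              100 * x$fractions[["ro5_mw"]], 100 * x$fractions[["ro5_clogp"]]))
  cat(sprintf("  rule-of-3 (all five) : %5.1f%%\n",
              100 * x$fractions[["ro3_all"]]))
  invisible(x)
}

#' Write / read building-block tables and catalogs as TSV
#'
#' Plain tab-separated text with a header row. The catalog writer stores
#' one row per member (member_id, aa_id, ca_id, tag); building-block tables
#' carry tags and properties, so a catalog can be reconstituted from its
#' two BB tables with [enumerate_library()].
#'
#' @param x a `del_bb_set`.
#' @param path output file.
#' @return `read_bb_tsv` returns a `del_bb_set`; writers return the path
#'   invisibly.
#' @export
write_bb_tsv <- function(x, path) {
  stopifnot(inherits(x, "del_bb_set"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bb_tsv
#' @export
read_bb_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(bb_id = "character",
                                         tag = "character"))
  building_blocks(df$bb_id, df$cycle[1], df$tag, df$mw, df$clogp,
                  df$hbd, df$hba, df$rotb)
}

#' @rdname write_bb_tsv
#' @param catalog a `del_catalog`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "del_catalog"))
  utils::write.table(
    catalog$members[c("member_id", "aa_id", "ca_id", "tag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
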