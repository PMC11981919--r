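# Mutation channel conventions: 96 single-base-substitution (SBS) classes in
# pyrimidine-centred trinucleotide context, and the 83 small-indel (ID) classes.

BASES <- c("A", "C", "G", "T")
SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 SBS channel labels in conventional order
#'
#' Substitution-major order (C>A, C>G, C>T, T>A, T>C, T>G), each with the 16
#' flanking contexts in alphabetical order, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBS, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }), use.names = FALSE)
}

#' The 83 ID channel labels in conventional order
#'
#' Single-base deletions/insertions at C/T homopolymers (run length coded 0-5,
#' capped), longer deletions/insertions at repeats, and microhomology-flanked
#' deletions, e.g. `"1:Del:T:5"`.
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  hp <- 0:5
  c(
    paste0("1:Del:C:", hp), paste0("1:Del:T:", hp),
    paste0("1:Ins:C:", hp), paste0("1:Ins:T:", hp),
    unlist(lapply(2:5, function(l) paste0(l, ":Del:R:", hp))),
    unlist(lapply(2:5, function(l) paste0(l, ":Ins:R:", hp))),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5)
  )
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(b)
    paste(rev(b), collapse = ""), character(1)))
}

#' Map an SNV with trinucleotide context to its SBS channel
#'
#' Mutations with a purine reference base are reverse-complemented into the
#' pyrimidine-centred convention.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Three-base reference context centred on the variant.
#' @return Channel label, or `NA_character_` if the input is not a valid SNV
#'   (non-ACGT bases, ref == alt, or context not matching ref).
#' @export
sbs_channel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    ref %in% BASES & alt %in% BASES & ref != alt &
    nchar(context) == 3 & substr(context, 2, 2) == ref &
    !grepl("[^ACGT]", context)
  if (any(ok)) {
    r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
    pur <- r %in% c("A", "G")
    r[pur] <- chartr("ACGT", "TGCA", r[pur])
    a[pur] <- chartr("ACGT", "TGCA", a[pur])
    ctx[pur] <- revcomp(ctx[pur])
    out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  }
  out
}

# Inverse of sbs_channel for the generator: a representative (ref, alt,
# context) triple for each channel label.
channel_to_snv <- function(channel) {
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  context <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))
  data.frame(ref = ref, alt = alt, context = context,
             stringsAsFactors = FALSE)
}

#' Map a 1-bp indel at a homopolymer to its ID channel
#'
#' @param type `"Del"` or `"Ins"`.
#' @param base The inserted/deleted base (`"A"`/`"T"`/`"C"`/`"G"`; purines are
#'   complemented into the C/T convention).
#' @param hp_len Length of the homopolymer run of `base` in the reference
#'   (for insertions, the run being extended; for deletions, the run
#'   containing the deleted base).
#' @return Channel label such as `"1:Del:T:5"`.
#' @export
id_channel <- function(type, base, hp_len) {
  n <- max(length(type), length(base), length(hp_len))
  type <- rep_len(type, n); base <- rep_len(toupper(base), n)
  hp_len <- rep_len(hp_len, n)
  base[base == "A"] <- "T"
  base[base == "G"] <- "C"
  idx <- ifelse(type == "Del", pmin(pmax(hp_len - 1, 0), 5),
                pmin(pmax(hp_len, 0), 5))
  out <- paste0("1:", type, ":", base, ":", idx)
  out[!(type %in% c("Del", "Ins")) | !(base %in% c("C", "T"))] <- NA_character_
  out
}

# Homopolymer annotations (type, base, hp_len) that map back to each 1-bp ID
# channel via id_channel(); generator use.
channel_id_annotation <- function(channel) {
  parts <- do.call(rbind, strsplit(channel, ":", fixed = TRUE))
  idx <- as.integer(parts[, 4])
  data.frame(
    indel_type = parts[, 2],
    indel_base = parts[, 3],
    hp_len = ifelse(parts[, 2] == "Del", idx + 1L, idx),
    stringsAsFactors = FALSE
  )
}

# Representative ref/alt strings for 1-bp ID channels (generator use).
channel_to_indel <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)
  ref <- alt <- character(length(channel))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p[1] == "1" && p[3] %in% c("C", "T")) {
      idx <- as.integer(p[4])
      if (p[2] == "Del") {
        run <- strrep(p[3], idx + 1L)
        ref[i] <- paste0("A", run)
        alt[i] <- paste0("A", substr(run, 2, nchar(run)))
      } else {
        run <- strrep(p[3], idx)
        ref[i] <- paste0("A", run)
        alt[i] <- paste0("A", p[3], run)
      }
    } else {
      len <- suppressWarnings(as.integer(p[1]))
      if (is.na(len)) len <- 2L
      if (p[2] == "Del") { ref[i] <- paste0("A", strrep("N", len)); alt[i] <- "A" }
      else { ref[i] <- "A"; alt[i] <- paste0("A", strrep("N", len)) }
    }
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}
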