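# Synthetic reference signature profiles.
#
# The package does not redistribute COSMIC reference tables. For simulation
# and testing it builds a deterministic set of synthetic profiles that share
# the COSMIC channel conventions, naming and table format, and reproduce the
# qualitative features that matter for deconvolution: a CpG-focused C>T
# clock-like signature (SBS1), an oxidative-damage-like C>A signature (SBS18),
# flat and mutually similar background signatures (SBS5, SBS40a, SBS40c, which
# downstream analyses report merged as SBS5/40), plus peaked decoys.

# deterministic smooth ripple across the 16 contexts of a substitution class;
# avoids exact collinearity between flat profiles without randomness
.ripple <- function(amp, phase) 1 + amp * sin(2 * pi * (0:15) / 16 + phase)

.sbs_profile <- function(class_weights, amp = 0.25, phase = 0) {
  w <- rep(class_weights / 16, each = 16) * rep(.ripple(amp, phase), 6)
  w / sum(w)
}

.peaked <- function(channels, peaks, peak_mass = 0.85) {
  w <- setNames(rep((1 - peak_mass) / 96, 96), channels)
  w[names(peaks)] <- w[names(peaks)] + peak_mass * peaks / sum(peaks)
  w / sum(w)
}

#' Synthetic reference signatures
#'
#' A deterministic, package-built stand-in for a COSMIC-style reference
#' signature table (channels x signatures, columns summing to 1). SBS profiles
#' cover the signatures used in signature fitting of gastric glands (SBS1,
#' SBS2, SBS3, SBS5, SBS13, SBS17a, SBS17b, SBS18, SBS28, SBS40a, SBS40c); ID
#' profiles cover ID1, ID2, ID5, ID6, ID9, ID12 and ID14. These are synthetic
#' emulations, not the COSMIC v3.4 estimates.
#'
#' @param class `"SBS"` (96 channels) or `"ID"` (83 channels).
#' @return Numeric matrix with channel rownames and signature colnames;
#'   each column sums to 1.
#' @export
synthetic_signatures <- function(class = c("SBS", "ID")) {
  class <- match.arg(class)
  if (class == "SBS") {
    ch <- sbs96_channels()
    ctg <- paste0(BASES, "[C>T]G")   # CpG C>T channels
    sbs1 <- .peaked(ch, setNames(c(0.30, 0.27, 0.24, 0.19), ctg), 0.88)
    sbs2 <- .peaked(ch, c("T[C>T]A" = 0.45, "T[C>T]T" = 0.35,
                          "T[C>T]C" = 0.12, "T[C>T]G" = 0.08), 0.85)
    sbs13 <- .peaked(ch, c("T[C>G]A" = 0.42, "T[C>G]T" = 0.40,
                           "T[C>G]C" = 0.18), 0.85)
    sbs18 <- local({
      # C>A dominated with context structure
      w <- setNames(rep(0.10 / 96, 96), ch)
      ca <- grep("C>A", ch, fixed = TRUE, value = TRUE)
      ripple <- .ripple(0.6, 1.1)
      w[ca] <- w[ca] + 0.90 * ripple / sum(ripple)
      w / sum(w)
    })
    sbs17a <- .peaked(ch, c("T[T>A]T" = 0.5, "C[T>A]T" = 0.3,
                            "A[T>A]T" = 0.2), 0.8)
    sbs17b <- .peaked(ch, c("T[T>G]T" = 0.55, "C[T>G]T" = 0.30,
                            "G[T>G]T" = 0.15), 0.8)
    sbs28 <- .peaked(ch, c("T[T>G]C" = 0.6, "C[T>G]C" = 0.4), 0.75)
    sbs3 <- .sbs_profile(c(0.18, 0.20, 0.14, 0.18, 0.15, 0.15), 0.20, 0.4)
    sbs5 <- .sbs_profile(c(0.10, 0.08, 0.25, 0.08, 0.38, 0.11), 0.25, 1.3)
    sbs40a <- .sbs_profile(c(0.25, 0.10, 0.18, 0.12, 0.22, 0.13), 0.25, 2.2)
    sbs40c <- .sbs_profile(c(0.15, 0.08, 0.12, 0.10, 0.20, 0.35), 0.25, 3.1)
    m <- cbind(SBS1 = sbs1, SBS2 = sbs2, SBS3 = sbs3, SBS5 = sbs5,
               SBS13 = sbs13, SBS17a = sbs17a, SBS17b = sbs17b,
               SBS18 = sbs18, SBS28 = sbs28, SBS40a = sbs40a,
               SBS40c = sbs40c)
    rownames(m) <- ch
  } else {
    ch <- id83_channels()
    pk <- function(peaks, mass = 0.8) .peaked_id(ch, peaks, mass)
    id1 <- pk(c("1:Ins:T:5" = 0.45, "1:Ins:T:4" = 0.30, "1:Ins:T:3" = 0.15,
                "1:Ins:C:4" = 0.10), 0.90)
    id2 <- pk(c("1:Del:T:5" = 0.50, "1:Del:T:4" = 0.28, "1:Del:T:3" = 0.14,
                "1:Del:C:4" = 0.08), 0.90)
    id5 <- pk(c("1:Del:T:1" = 0.25, "1:Del:T:2" = 0.25, "1:Ins:T:1" = 0.20,
                "1:Del:C:1" = 0.15, "1:Ins:C:1" = 0.15), 0.70)
    id6 <- pk(c("5:Del:M:1" = 0.30, "5:Del:M:2" = 0.25, "4:Del:M:1" = 0.25,
                "3:Del:M:1" = 0.20), 0.85)
    id9 <- pk(c("1:Del:C:0" = 0.35, "1:Del:T:0" = 0.35, "2:Del:R:0" = 0.30),
              0.75)
    id12 <- pk(c("2:Ins:R:1" = 0.40, "2:Ins:R:2" = 0.30, "3:Ins:R:1" = 0.30),
               0.80)
    id14 <- pk(c("4:Ins:R:0" = 0.5, "5:Ins:R:0" = 0.5), 0.8)
    m <- cbind(ID1 = id1, ID2 = id2, ID5 = id5, ID6 = id6, ID9 = id9,
               ID12 = id12, ID14 = id14)
    rownames(m) <- ch
  }
  stopifnot(all(abs(colSums(m) - 1) < 1e-9))
  m
}

.peaked_id <- function(channels, peaks, peak_mass) {
  w <- setNames(rep((1 - peak_mass) / length(channels), length(channels)),
                channels)
  w[names(peaks)] <- w[names(peaks)] + peak_mass * peaks / sum(peaks)
  w / sum(w)
}

#' Read a COSMIC-format signature table
#'
#' Expects a TSV with a channel-label column (named `Type`, `MutationType`,
#' or the first column) followed by one numeric column per signature.
#' Columns are renormalized to sum to 1.
#'
#' @param path Path to the TSV file.
#' @return Matrix channels x signatures.
#' @export
read_signatures <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labcol <- intersect(c("Type", "MutationType", "MutationsType"), names(d))
  labcol <- if (length(labcol)) labcol[1] else names(d)[1]
  m <- as.matrix(d[setdiff(names(d), labcol)])
  rownames(m) <- d[[labcol]]
  if (any(m < 0)) stop("negative entries in signature table")
  sweep(m, 2, colSums(m), "/")
}

#' Write a signature table in COSMIC format
#'
#' @param sigs Matrix channels x signatures with channel rownames.
#' @param path Output TSV path.
#' @export
write_signatures <- function(sigs, path) {
  d <- data.frame(Type = rownames(sigs), sigs, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
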