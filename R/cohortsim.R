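# Synthetic cohort generator.
#
# Emulates the statistical structure of a microdissected gastric gland cohort:
# monoclonal glands with VAF peaks in the 0.25-0.5 range, ~23x median depth,
# donor-shared germline heterozygous sites, cross-sample sequencing artifacts
# with low overdispersion, age-proportional mutation burdens accelerated in
# intestinal metaplasia, recurrent trisomies with 2/3 vs 1/3 haplotype VAFs,
# and occasional driver mutations. Every quantity downstream stages estimate
# is recorded as ground truth.

AUTOSOMES <- paste0("chr", c(1:19, 21:22))
GASTRIC_SITES <- c("cardia", "fundus", "body", "antrum")
CI_GRADES <- c("absent", "mild", "moderate", "severe")
SELECTION_GENES <- c("ARID1A", "ARID1B", "ARID2", "CTNNB1", "EEF1A1",
                     "LIPF", "KDM6A")

#' Simulation configuration
#'
#' Defaults describe a non-cancer cohort: stem cells accrue 27.8 SNVs and 2.0
#' indels per year; metaplastic glands carry 2.8-fold (SNV) and 4.4-fold
#' (indel) accelerated burdens, driven by signature-specific accelerations
#' (SBS1 x3, SBS18 x8, SBS5/40 x1; ID1 x2, ID2 x8.5, ID5 x1) whose mixture
#' composes exactly to the overall folds; sequencing depth has median 23.
#'
#' @param n_donors Number of donors.
#' @param age_range Min/max donor age in years (ages drawn uniformly).
#' @param glands_per_donor Non-metaplastic glands per donor.
#' @param n_metaplastic Total metaplastic glands, assigned round-robin to
#'   donors (antrum site).
#' @param snv_rate,indel_rate Mutations per year of life.
#' @param metaplasia_snv_fold,metaplasia_indel_fold Burden multipliers for
#'   metaplastic glands.
#' @param baseline_signature_mix Named proportions over SBS signature groups
#'   (must sum to 1).
#' @param signature_accel Named per-signature fold accelerations applied in
#'   metaplastic glands.
#' @param id_signature_mix,id_signature_accel Same for indel signatures.
#' @param depth_median Median sequencing depth (reads).
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   distribution.
#' @param clonal_fraction_range Range of the fraction of epithelial cells in
#'   the dominant clone.
#' @param contamination Stromal (non-epithelial) cell fraction.
#' @param n_germline_sites Germline heterozygous sites per donor.
#' @param n_phased_snps How many of the germline sites lie on chr20 with
#'   known haplotype (phased-SNP truth).
#' @param artifact_rate Expected number of recurrent artifact sites per donor.
#' @param artifact_vaf_range VAF range of artifact sites.
#' @param base_error Per-read error rate rendered at non-variant sites.
#' @param trisomy_prob Probability that a gland carries a chr20 trisomy.
#' @param trisomy_timing Molecular timing of the gain, fraction in \[0, 1\].
#' @param trisomy_chrom_fraction Fraction of somatic mutations on chr20.
#' @param donor_lognorm_sd SD (log scale) of the mean-one lognormal donor
#'   rate factor (donor random effect).
#' @param driver_prob Probability that a gland carries one driver mutation.
#' @param min_reads Minimum variant-supporting reads for a variant to be
#'   emitted as called (calling emulation).
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical cohorts.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 12,
                       age_range = c(25, 80),
                       glands_per_donor = 7,
                       n_metaplastic = 0,
                       snv_rate = 27.8,
                       indel_rate = 2.0,
                       metaplasia_snv_fold = 2.8,
                       metaplasia_indel_fold = 4.4,
                       baseline_signature_mix = c("SBS1" = 0.30,
                                                  "SBS18" = 6 / 35,
                                                  "SBS5/40" = 1 - 0.30 - 6 / 35),
                       signature_accel = c("SBS1" = 3, "SBS18" = 8,
                                           "SBS5/40" = 1),
                       id_signature_mix = c("ID1" = 0.4, "ID2" = 0.4,
                                            "ID5" = 0.2),
                       id_signature_accel = c("ID1" = 2, "ID2" = 8.5,
                                              "ID5" = 1),
                       depth_median = 23,
                       depth_dispersion = 30,
                       clonal_fraction_range = c(0.6, 0.95),
                       contamination = 0.05,
                       n_germline_sites = 200,
                       n_phased_snps = 40,
                       artifact_rate = 50,
                       artifact_vaf_range = c(0.02, 0.10),
                       base_error = 1e-3,
                       trisomy_prob = 0.1,
                       trisomy_timing = 0.2,
                       trisomy_chrom_fraction = 0.025,
                       donor_lognorm_sd = 0.1,
                       driver_prob = 0.1,
                       min_reads = 4,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid sim_config field '", field, "': ", msg,
                  call. = FALSE)
  for (f in c("snv_rate", "indel_rate", "artifact_rate", "base_error",
              "metaplasia_snv_fold", "metaplasia_indel_fold"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
        f, "must be a single non-negative number")
  chk(abs(sum(cfg$baseline_signature_mix) - 1) < 1e-9,
      "baseline_signature_mix", "must sum to 1")
  chk(abs(sum(cfg$id_signature_mix) - 1) < 1e-9,
      "id_signature_mix", "must sum to 1")
  chk(all(names(cfg$baseline_signature_mix) %in% names(cfg$signature_accel)),
      "signature_accel", "must cover baseline_signature_mix names")
  chk(cfg$trisomy_timing >= 0 && cfg$trisomy_timing <= 1,
      "trisomy_timing", "must be in [0, 1]")
  chk(cfg$trisomy_prob >= 0 && cfg$trisomy_prob <= 1,
      "trisomy_prob", "must be in [0, 1]")
  chk(cfg$contamination >= 0 && cfg$contamination < 1,
      "contamination", "must be in [0, 1)")
  chk(length(cfg$age_range) == 2 && cfg$age_range[1] > 0 &&
        diff(cfg$age_range) >= 0, "age_range", "must be positive (min, max)")
  chk(length(cfg$clonal_fraction_range) == 2 &&
        cfg$clonal_fraction_range[1] > 0 &&
        cfg$clonal_fraction_range[2] <= 1,
      "clonal_fraction_range", "must lie in (0, 1]")
  chk(cfg$depth_median >= 1, "depth_median", "must be >= 1")
  chk(cfg$n_phased_snps <= cfg$n_germline_sites, "n_phased_snps",
      "cannot exceed n_germline_sites")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

# negative-binomial mu whose distribution has the requested median: the
# median equals med iff F(med - 1) < 0.5 <= F(med); F is decreasing in mu,
# so mu lies in (mu_lower, mu_upper]; take the midpoint
nb_mu_for_median <- function(med, size) {
  rng <- c(1e-3, 4 * med + 10)
  mu_upper <- uniroot(function(mu)
    pnbinom(med, size = size, mu = mu) - 0.5, rng)$root
  mu_lower <- if (med >= 1)
    uniroot(function(mu)
      pnbinom(med - 1, size = size, mu = mu) - 0.5, rng)$root
  else 1e-3
  (mu_lower + mu_upper) / 2
}

# expected VAF of a clonal variant given cell fraction, trisomy state
expected_vaf <- function(cell_fraction, contamination, on_trisomy = FALSE,
                         duplicated = FALSE) {
  cfe <- cell_fraction * (1 - contamination)
  ifelse(on_trisomy,
         ifelse(duplicated, 2 * cfe, cfe) / (3 * cfe + 2 * (1 - cfe)),
         0.5 * cfe)
}

# expected VAF of a germline het SNP in a sample where a fraction cfe of all
# cells carries a trisomy of its chromosome
germline_trisomy_vaf <- function(cfe, on_duplicated_hap) {
  ifelse(on_duplicated_hap, (1 + cfe) / (2 + cfe), 1 / (2 + cfe))
}

.mix_for <- function(mix, accel, metaplasia) {
  if (!metaplasia) return(mix)
  m <- mix * accel[names(mix)]
  m / sum(m)
}

#' Simulate the ground truth of one gland
#'
#' Draws the mutation count from a Poisson with mean rate x age x fold,
#' assigns signatures and channels, chromosome labels, and (for trisomic
#' glands) duplicated flags for chr20 mutations acquired before the gain.
#'
#' Consumes the current RNG stream; seed via `set.seed()` or use
#' [simulate_cohort()].
#'
#' @param donor_profile List with `donor` (id), `age` (years, > 0) and
#'   optionally `rate_factor` (mean-one donor effect, default 1).
#' @param config A [sim_config].
#' @param metaplasia,site,clonal_fraction Optional overrides; drawn from the
#'   config by default.
#' @return Object of class `gland_truth`: gland metadata plus a `mutations`
#'   data.frame (var_class, signature, channel, chrom, duplicated,
#'   cell_fraction, gene, consequence, indel annotations).
#' @export
simulate_gland <- function(donor_profile, config, metaplasia = FALSE,
                           site = NULL, clonal_fraction = NULL) {
  age <- donor_profile$age
  if (is.null(age) || age <= 0) stop("donor age must be > 0")
  rf <- donor_profile$rate_factor %||% 1
  if (is.null(site))
    site <- if (metaplasia) "antrum" else sample(GASTRIC_SITES, 1)
  if (is.null(clonal_fraction))
    clonal_fraction <- runif(1, config$clonal_fraction_range[1],
                             config$clonal_fraction_range[2])
  ci_grade <- sample(CI_GRADES, 1, prob = c(0.4, 0.3, 0.2, 0.1))

  trisomy <- NULL
  if (runif(1) < config$trisomy_prob)
    trisomy <- list(chrom = "chr20",
                    parental_copy = sample(c("A", "B"), 1),
                    timing = config$trisomy_timing)

  n_snv <- rpois(1, config$snv_rate * age * rf *
                   if (metaplasia) config$metaplasia_snv_fold else 1)
  n_ind <- rpois(1, config$indel_rate * age * rf *
                   if (metaplasia) config$metaplasia_indel_fold else 1)

  sbs_mix <- .mix_for(config$baseline_signature_mix, config$signature_accel,
                      metaplasia)
  id_mix <- .mix_for(config$id_signature_mix, config$id_signature_accel,
                     metaplasia)

  refs_sbs <- .generator_sbs_profiles(names(sbs_mix))
  refs_id <- .generator_id_profiles(names(id_mix))

  draw_class <- function(n, mix, refs) {
    if (n == 0)
      return(data.frame(signature = character(0), channel = character(0)))
    sigs <- sample(names(mix), n, replace = TRUE, prob = mix)
    ch <- character(n)
    for (s in unique(sigs)) {
      idx <- which(sigs == s)
      ch[idx] <- sample(rownames(refs), length(idx), replace = TRUE,
                        prob = refs[, s])
    }
    data.frame(signature = sigs, channel = ch, stringsAsFactors = FALSE)
  }
  snvs <- draw_class(n_snv, sbs_mix, refs_sbs)
  inds <- draw_class(n_ind, id_mix, refs_id)
  mut <- rbind(
    if (nrow(snvs)) cbind(snvs, var_class = "SNV"),
    if (nrow(inds)) cbind(inds, var_class = "indel")
  )
  if (is.null(mut))
    mut <- data.frame(signature = character(0), channel = character(0),
                      var_class = character(0))

  n <- nrow(mut)
  mut$chrom <- if (n) ifelse(runif(n) < config$trisomy_chrom_fraction,
                             "chr20", sample(AUTOSOMES, n, replace = TRUE))
               else character(0)
  mut$duplicated <- rep(FALSE, n)
  if (!is.null(trisomy) && n) {
    on20 <- mut$chrom == "chr20"
    t <- trisomy$timing
    # pre-gain mutations arise on 2 copies over time t, post-gain on 3 copies
    # over 1 - t; a pre-gain mutation sits on the duplicated copy w.p. 1/2
    pre <- on20 & runif(n) < (2 * t) / (3 - t)
    mut$duplicated <- pre & runif(n) < 0.5
  }
  mut$cell_fraction <- rep(clonal_fraction, n)
  mut$gene <- rep(NA_character_, n)
  mut$consequence <- rep(NA_character_, n)
  if (runif(1) < config$driver_prob) {
    drv <- data.frame(
      signature = NA_character_, channel = sample(sbs96_channels(), 1),
      var_class = "SNV", chrom = sample(AUTOSOMES, 1), duplicated = FALSE,
      cell_fraction = clonal_fraction,
      gene = sample(SELECTION_GENES, 1),
      consequence = sample(c("missense", "nonsense", "frameshift", "splice"),
                           1, prob = c(0.4, 0.3, 0.2, 0.1)),
      stringsAsFactors = FALSE)
    mut <- rbind(mut, drv)
  }

  structure(list(donor = donor_profile$donor %||% "D", age = age,
                 site = site, metaplasia = metaplasia, ci_grade = ci_grade,
                 clonal_fraction = clonal_fraction, trisomy = trisomy,
                 true_snv = n_snv, true_indel = n_ind, mutations = mut),
            class = "gland_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signature profiles used for channel sampling; "SBS5/40" is the mean of the
# flat background profiles
.generator_sbs_profiles <- function(groups) {
  refs <- synthetic_signatures("SBS")
  out <- sapply(groups, function(g) {
    if (g == "SBS5/40")
      rowMeans(refs[, c("SBS5", "SBS40a", "SBS40c")])
    else refs[, g]
  })
  rownames(out) <- rownames(refs)
  out
}

.generator_id_profiles <- function(groups) {
  refs <- synthetic_signatures("ID")
  out <- refs[, groups, drop = FALSE]
  out
}

#' Render read counts for one gland's mutations
#'
#' Depth is drawn from a negative binomial with the configured median;
#' variant-supporting reads from a binomial at the expected VAF given the
#' mutation's cell fraction, local copy number (2/3 vs 1/3 scaling for
#' duplicated vs non-duplicated trisomic variants) and stromal contamination.
#'
#' @param truth A `gland_truth` from [simulate_gland()].
#' @param config A [sim_config].
#' @return data.frame with `nv`, `nr` and `exp_vaf` per mutation.
#' @export
render_reads <- function(truth, config) {
  mut <- truth$mutations
  n <- nrow(mut)
  mu <- nb_mu_for_median(config$depth_median, config$depth_dispersion)
  nr <- rnbinom(n, size = config$depth_dispersion, mu = mu)
  on_tri <- !is.null(truth$trisomy) & mut$chrom == "chr20"
  p <- expected_vaf(mut$cell_fraction, config$contamination,
                    on_trisomy = on_tri, duplicated = mut$duplicated)
  nv <- rbinom(n, nr, p)
  data.frame(nv = nv, nr = nr, exp_vaf = p)
}

#' Simulate a cohort of microdissected glands with known ground truth
#'
#' Generates donors, glands, germline heterozygous sites, recurrent artifact
#' sites and per-sample read counts, then emits the *called* variants (those
#' reaching `min_reads` supporting reads) as one count matrix per donor.
#'
#' @param config A [sim_config].
#' @param seed Optional override of `config$seed`.
#' @return Object of class `synthetic_cohort` with elements:
#'   \describe{
#'     \item{metadata}{per-sample data.frame (donor, age, site, metaplasia,
#'       ci_grade, area_mm2, clonal_fraction, trisomy fields, true mutation
#'       counts).}
#'     \item{donors}{named list; per donor a `count_matrix` and an aligned
#'       `truth` data.frame (origin somatic/germline/artifact, origin sample,
#'       signature, duplicated flag, cell fraction, haplotype).}
#'     \item{phased_snps}{haplotype truth for chr20 germline SNPs.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  set.seed(if (!is.null(seed)) seed else config$seed)
  nd <- config$n_donors
  donor_ids <- sprintf("D%02d", seq_len(nd))
  ages <- runif(nd, config$age_range[1], config$age_range[2])
  sdl <- config$donor_lognorm_sd
  rate_factor <- if (sdl > 0)
    rlnorm(nd, meanlog = -sdl^2 / 2, sdlog = sdl) else rep(1, nd)

  n_meta <- rep(0L, nd)
  if (config$n_metaplastic > 0)
    n_meta <- tabulate(rep(seq_len(nd),
                           length.out = config$n_metaplastic), nd)

  mu_depth <- nb_mu_for_median(config$depth_median, config$depth_dispersion)
  meta_rows <- list()
  donors <- list()
  phased <- list()

  for (d in seq_len(nd)) {
    profile <- list(donor = donor_ids[d], age = ages[d],
                    rate_factor = rate_factor[d])
    n_g <- config$glands_per_donor + n_meta[d]
    is_meta <- c(rep(FALSE, config$glands_per_donor), rep(TRUE, n_meta[d]))
    glands <- lapply(seq_len(n_g), function(g)
      simulate_gland(profile, config, metaplasia = is_meta[g]))
    sam <- sprintf("%s_g%02d", donor_ids[d], seq_len(n_g))

    dres <- .assemble_donor(donor_ids[d], glands, sam, config, mu_depth)
    donors[[donor_ids[d]]] <- dres[c("count_matrix", "truth")]
    phased[[d]] <- dres$phased

    meta_rows[[d]] <- data.frame(
      sample = sam, donor = donor_ids[d], age = ages[d],
      site = vapply(glands, `[[`, "", "site"),
      metaplasia = is_meta,
      ci_grade = vapply(glands, `[[`, "", "ci_grade"),
      area_mm2 = rlnorm(n_g, log(0.05), 0.5),
      clonal_fraction = vapply(glands, `[[`, 0, "clonal_fraction"),
      trisomy = vapply(glands, function(g) !is.null(g$trisomy), FALSE),
      trisomy_hap = vapply(glands, function(g)
        if (is.null(g$trisomy)) NA_character_ else g$trisomy$parental_copy,
        ""),
      trisomy_timing = vapply(glands, function(g)
        if (is.null(g$trisomy)) NA_real_ else g$trisomy$timing, 0),
      true_snv = vapply(glands, `[[`, 0, "true_snv"),
      true_indel = vapply(glands, `[[`, 0, "true_indel"),
      stringsAsFactors = FALSE)
  }

  structure(list(metadata = do.call(rbind, meta_rows),
                 donors = donors,
                 phased_snps = do.call(rbind, phased),
                 config = config),
            class = "synthetic_cohort")
}

# Build one donor's count matrix: somatic mutations of each gland, shared
# germline sites, shared artifact sites; render reads in every sample; keep
# variants reaching min_reads support ("called").
.assemble_donor <- function(donor_id, glands, sam, config, mu_depth) {
  n_g <- length(glands)
  cfe <- vapply(glands, function(g)
    g$clonal_fraction * (1 - config$contamination), 0)
  trisomic <- vapply(glands, function(g) !is.null(g$trisomy), FALSE)
  tri_hap <- vapply(glands, function(g)
    if (is.null(g$trisomy)) NA_character_ else g$trisomy$parental_copy, "")

  # --- somatic rows -----------------------------------------------------
  som <- lapply(seq_len(n_g), function(g) {
    m <- glands[[g]]$mutations
    if (!nrow(m)) return(NULL)
    m$origin_sample <- sam[g]
    m
  })
  som <- do.call(rbind, som[!vapply(som, is.null, TRUE)])
  n_som <- if (is.null(som)) 0L else nrow(som)

  # --- germline rows ----------------------------------------------------
  n_gl <- config$n_germline_sites
  n_ph <- config$n_phased_snps
  gl <- data.frame(
    chrom = c(rep("chr20", n_ph),
              sample(AUTOSOMES, n_gl - n_ph, replace = TRUE)),
    haplotype = c(rep(c("A", "B"), length.out = n_ph),
                  rep(NA_character_, n_gl - n_ph)),
    stringsAsFactors = FALSE)

  # --- artifact rows ----------------------------------------------------
  n_art <- rpois(1, config$artifact_rate)
  art_vaf <- runif(n_art, config$artifact_vaf_range[1],
                   config$artifact_vaf_range[2])
  art_class <- sample(c("SNV", "indel"), n_art, replace = TRUE,
                      prob = c(0.8, 0.2))

  n_tot <- n_som + n_gl + n_art
  origin <- c(rep("somatic", n_som), rep("germline", n_gl),
              rep("artifact", n_art))

  # expected VAF matrix (variants x samples)
  P <- matrix(config$base_error, n_tot, n_g)
  if (n_som) {
    g_idx <- match(som$origin_sample, sam)
    on_tri <- trisomic[g_idx] & som$chrom == "chr20"
    P[cbind(seq_len(n_som), g_idx)] <-
      expected_vaf(som$cell_fraction, config$contamination,
                   on_trisomy = on_tri, duplicated = som$duplicated)
  }
  for (g in seq_len(n_g)) {
    rows <- n_som + seq_len(n_gl)
    p_gl <- rep(0.5, n_gl)
    if (trisomic[g] && n_ph > 0) {
      on20 <- gl$chrom == "chr20"
      p_gl[on20] <- germline_trisomy_vaf(
        cfe[g], gl$haplotype[on20] == tri_hap[g])
    }
    P[rows, g] <- p_gl
    if (n_art) P[n_som + n_gl + seq_len(n_art), g] <- art_vaf
  }

  NR <- matrix(rnbinom(n_tot * n_g, size = config$depth_dispersion,
                       mu = mu_depth), n_tot, n_g)
  NV <- matrix(rbinom(n_tot * n_g, NR, P), n_tot, n_g)
  colnames(NV) <- colnames(NR) <- sam

  # diploid mask: chr20 loci are not largely diploid in trisomic samples
  chroms <- c(if (n_som) som$chrom, gl$chrom,
              sample(AUTOSOMES, n_art, replace = TRUE))
  diploid <- matrix(TRUE, n_tot, n_g)
  if (any(trisomic))
    diploid[chroms == "chr20", trisomic] <- FALSE

  # calling emulation: somatic kept if supported in their gland; shared
  # (germline/artifact) sites kept if any sample reaches min_reads
  keep <- rep(TRUE, n_tot)
  if (n_som) {
    g_idx <- match(som$origin_sample, sam)
    keep[seq_len(n_som)] <- NV[cbind(seq_len(n_som), g_idx)] >=
      config$min_reads
  }
  shared <- n_som + seq_len(n_gl + n_art)
  if (length(shared))
    keep[shared] <- apply(NV[shared, , drop = FALSE], 1, max) >=
      config$min_reads

  # variant annotation table
  pos <- sample.int(2^28, n_tot)
  var_class <- c(if (n_som) som$var_class, rep("SNV", n_gl), art_class)
  channel <- c(if (n_som) som$channel,
               sample(sbs96_channels(), n_gl, replace = TRUE),
               ifelse(art_class == "SNV",
                      sample(sbs96_channels(), n_art, replace = TRUE),
                      sample(id83_channels()[1:24], n_art, replace = TRUE)))
  is_snv <- var_class == "SNV"
  ref <- alt <- context <- rep(NA_character_, n_tot)
  indel_type <- indel_base <- rep(NA_character_, n_tot)
  hp_len <- rep(NA_integer_, n_tot)
  if (any(is_snv)) {
    s <- channel_to_snv(channel[is_snv])
    ref[is_snv] <- s$ref; alt[is_snv] <- s$alt; context[is_snv] <- s$context
  }
  if (any(!is_snv)) {
    idl <- channel_to_indel(channel[!is_snv])
    ref[!is_snv] <- idl$ref; alt[!is_snv] <- idl$alt
    ann <- channel_id_annotation(channel[!is_snv])
    indel_type[!is_snv] <- ann$indel_type
    indel_base[!is_snv] <- ann$indel_base
    hp_len[!is_snv] <- ann$hp_len
  }
  variants <- data.frame(
    chrom = chroms, pos = pos, ref = ref, alt = alt, var_class = var_class,
    context = context, channel = channel,
    indel_type = indel_type, indel_base = indel_base, hp_len = hp_len,
    asmd = round(runif(n_tot, 150, 250)), clpm = rep(0, n_tot),
    gene = c(if (n_som) som$gene, rep(NA_character_, n_gl + n_art)),
    consequence = c(if (n_som) som$consequence,
                    rep(NA_character_, n_gl + n_art)),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    origin = origin,
    origin_sample = c(if (n_som) som$origin_sample,
                      rep(NA_character_, n_gl + n_art)),
    signature = c(if (n_som) som$signature,
                  rep(NA_character_, n_gl + n_art)),
    duplicated = c(if (n_som) som$duplicated, rep(FALSE, n_gl + n_art)),
    cell_fraction = c(if (n_som) som$cell_fraction,
                      rep(NA_real_, n_gl + n_art)),
    haplotype = c(rep(NA_character_, n_som), gl$haplotype,
                  rep(NA_character_, n_art)),
    stringsAsFactors = FALSE)

  cm <- count_matrix(variants[keep, , drop = FALSE],
                     NV[keep, , drop = FALSE], NR[keep, , drop = FALSE],
                     diploid[keep, , drop = FALSE])
  ph <- if (n_ph > 0)
    data.frame(donor = donor_id, chrom = "chr20",
               pos = pos[n_som + seq_len(n_ph)],
               haplotype = gl$haplotype[seq_len(n_ph)],
               stringsAsFactors = FALSE)
  list(count_matrix = cm, truth = truth[keep, , drop = FALSE], phased = ph)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$donors), "donors,",
      nrow(x$metadata), "glands\n")
  cat("  metaplastic:", sum(x$metadata$metaplasia),
      " trisomic:", sum(x$metadata$trisomy), "\n")
  invisible(x)
}

#' Simulate phased-SNP counts for targeted panel samples
#'
#' Emulates the chr20 trisomy-detection setting: heterozygous SNPs phased into
#' haplotypes A and B, counted in panel microdissections that are either
#' diploid (both haplotype VAFs 0.5) or trisomic (2/3 vs 1/3, scaled by the
#' trisomic cell fraction).
#'
#' @param n_samples Number of panel microdissections.
#' @param n_snps Number of phased SNP sites.
#' @param depth Mean panel depth (negative binomial, size 30).
#' @param trisomic Logical vector (recycled) marking trisomic samples.
#' @param cell_fraction Fraction of cells carrying the trisomy.
#' @param duplicated_hap `"A"`/`"B"` per sample (recycled): which haplotype is
#'   duplicated.
#' @param seed Optional seed.
#' @return List with `snps` (chrom/pos/haplotype), `counts` (long data.frame:
#'   sample, haplotype, nv, nr) and `truth` (per-sample trisomy status).
#' @export
simulate_panel_counts <- function(n_samples, n_snps = 40, depth = 100,
                                  trisomic = FALSE, cell_fraction = 0.9,
                                  duplicated_hap = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trisomic <- rep_len(trisomic, n_samples)
  duplicated_hap <- rep_len(duplicated_hap, n_samples)
  cell_fraction <- rep_len(cell_fraction, n_samples)
  hap <- rep(c("A", "B"), length.out = n_snps)
  snps <- data.frame(chrom = "chr20", pos = sort(sample.int(6e7, n_snps)),
                     haplotype = hap, stringsAsFactors = FALSE)
  counts <- lapply(seq_len(n_samples), function(s) {
    nr <- rnbinom(n_snps, size = 30, mu = depth)
    p <- if (trisomic[s])
      germline_trisomy_vaf(cell_fraction[s], hap == duplicated_hap[s])
    else rep(0.5, n_snps)
    data.frame(sample = sprintf("P%03d", s), haplotype = hap,
               nv = rbinom(n_snps, nr, p), nr = nr,
               stringsAsFactors = FALSE)
  })
  list(snps = snps, counts = do.call(rbind, counts),
       truth = data.frame(sample = sprintf("P%03d", seq_len(n_samples)),
                          trisomic = trisomic,
                          duplicated_hap = duplicated_hap,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' One count-matrix TSV per donor, cohort metadata CSV, per-variant truth TSV
#' and phased-SNP TSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$metadata, file.path(outdir, "metadata.csv"),
                   row.names = FALSE)
  for (d in names(cohort$donors)) {
    write_count_matrix(cohort$donors[[d]]$count_matrix,
                       file.path(outdir, paste0("counts_", d, ".tsv")))
    write.table(cohort$donors[[d]]$truth,
                file.path(outdir, paste0("truth_", d, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$phased_snps))
    write.table(cohort$phased_snps, file.path(outdir, "phased_snps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
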