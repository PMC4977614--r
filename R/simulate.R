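# Gene-drop pedigree simulator: synthetic cohorts with one injected dominant
# causal variant (incomplete penetrance, phenocopies) plus decoy variants and
# simulated annotation scores. Everything downstream of a seed is
# deterministic, and member statuses are derived from observable phenotype
# only — never from hidden carrier truth.

#' Simulation specification
#'
#' The stated world of the simulator. Defaults emulate a three-generation
#' high-risk family of the kind the pipeline targets: a dominant causal
#' variant entering through one founder, late-onset disease, a handful of
#' sequenced relatives, and a background of rare and common decoy variants
#' gene-dropped from the founders.
#'
#' @param generations pedigree depth (default 3)
#' @param sibship children per reproducing couple (default 3)
#' @param n_decoys background decoy variants (default 200)
#' @param p_rare fraction of decoys that are rare family-private variants
#'   (one founder copy; default 0.7); the rest are common, founder frequency
#'   uniform on `common_freq_range`
#' @param rare_maf_max catalogue MAF ceiling for rare decoys (default 5e-4)
#' @param p_novel fraction of rare decoys absent from both frequency
#'   catalogues (default 0.3)
#' @param common_freq_range founder allele-frequency range of common decoys
#' @param causal_penetrance probability a causal carrier is affected
#'   (default 1)
#' @param phenocopy_rate probability a non-carrier is affected (default 0)
#' @param sequencing_subset `"all"` (default) or a character vector of
#'   member ids to treat as sequenced
#' @param min_cases,min_informative_meioses ascertainment: the causal drop
#'   is redrawn until at least this many sequenced affected members exist
#'   and the causal transmission involves at least this many informative
#'   meioses (families enter sequencing because they look Mendelian);
#'   defaults 3 and 4
#' @param onset_mean,onset_sd diagnosis-age distribution (years; 62, 10)
#' @param late_onset_age affected members diagnosed at or after this age are
#'   `CASE_POSSIBLE_PHENOCOPY` (default 78)
#' @param young_control_age unaffected members younger than this (or with
#'   >= 3 affected first-degree relatives) are `CONTROL_POSSIBLE_CARRIER`
#'   (default 55)
#' @param ref_year "today" for age computation (default 2015)
#' @param missing_gt_rate per-cell missing-genotype rate on decoys
#'   (default 0.02)
#' @param indel_rate fraction of decoys simulated as indels (default 0.08)
#' @param qual_fail_rate,depth_fail_rate,strand_fail_rate,indel_fail_rate
#'   designed technical-failure rates among decoys (defaults 0.05, 0.05,
#'   0.05, 0.3 of indels)
#' @param boundary_decoys plant a handful of decoys at exactly the
#'   documented strict thresholds (CADD 10/20/30, MAF 0.001, GERP 2.0 +
#'   PhastCons 0.3, mirSVR -0.1) to exercise boundary behaviour
#' @param causal_cadd_range,decoy_cadd_range scaled-CADD draws for the
#'   causal variant (top-0.1% tier) and decoys
#' @param p_deleterious,p_predictor_missing per-predictor call
#'   probabilities for decoys
#' @return object of class `simulation_spec`
#' @export
simulation_spec <- function(generations = 3, sibship = 3, n_decoys = 200,
                            p_rare = 0.7, rare_maf_max = 5e-4, p_novel = 0.3,
                            common_freq_range = c(0.05, 0.5),
                            causal_penetrance = 1, phenocopy_rate = 0,
                            sequencing_subset = "all",
                            min_cases = 3, min_informative_meioses = 4,
                            onset_mean = 62, onset_sd = 10,
                            late_onset_age = 78, young_control_age = 55,
                            ref_year = 2015,
                            missing_gt_rate = 0.02, indel_rate = 0.08,
                            qual_fail_rate = 0.05, depth_fail_rate = 0.05,
                            strand_fail_rate = 0.05, indel_fail_rate = 0.3,
                            boundary_decoys = TRUE,
                            causal_cadd_range = c(30, 45),
                            decoy_cadd_range = c(0, 35),
                            p_deleterious = 0.3, p_predictor_missing = 0.1) {
  stopifnot(generations >= 2, sibship >= 1, n_decoys >= 0,
            causal_penetrance >= 0, causal_penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            p_rare >= 0, p_rare <= 1)
  spec <- as.list(environment())
  structure(spec, class = "simulation_spec")
}

#' Simulate a pedigree from the template
#'
#' Builds an acyclic multi-generation pedigree: a founder couple, `sibship`
#' children per reproducing couple (the first two children of each sibship
#' marry a new married-in founder and reproduce), down to `generations`
#' levels. Sexes alternate and are consistent with parenthood; birth years
#' step ~28 years per generation. No statuses or affection are assigned
#' here — see [inject_causal()].
#'
#' @param spec a [simulation_spec()]
#' @param seed optional RNG seed (set for standalone reproducibility; leave
#'   `NULL` inside a seeded [simulate_cohort()] run)
#' @return a [pedigree()], all members unsequenced
#' @export
simulate_pedigree <- function(spec = simulation_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- character(); father <- character(); mother <- character()
  sex <- character(); birth <- integer()
  add <- function(i, f, m, s, b) {
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s); birth <<- c(birth, b)
  }
  base_year <- function(g) 1920L + (g - 1L) * 28L +
    sample(-3:3, 1L)
  add("G1I1", NA, NA, "male", base_year(1))
  add("G1S1", NA, NA, "female", base_year(1))
  couples <- list(c("G1I1", "G1S1"))
  for (g in 2:spec$generations) {
    next_couples <- list()
    ci <- 0L
    for (cp in couples) {
      pa <- cp[1]; ma <- cp[2]
      for (k in seq_len(spec$sibship)) {
        ci <- ci + 1L
        kid <- sprintf("G%dI%d", g, ci)
        ksex <- if (ci %% 2L == 1L) "female" else "male"
        add(kid, pa, ma, ksex, base_year(g))
        if (g < spec$generations && k <= 2L) {
          sp <- sprintf("G%dS%d", g, ci)
          add(sp, NA, NA, if (ksex == "female") "male" else "female",
              base_year(g))
          next_couples[[length(next_couples) + 1L]] <-
            if (ksex == "male") c(kid, sp) else c(sp, kid)
        }
      }
    }
    couples <- next_couples
  }
  pedigree(id = id, father = father, mother = mother, sex = sex,
           birth_year = birth)
}

# transmit genotypes down the pedigree given founder dosages;
# founder_dos: n_variants x n_founders matrix. Returns n x n_members.
gene_drop_core <- function(ped, founder_dos) {
  ord <- order(ped$generation)
  n <- nrow(founder_dos)
  gt <- matrix(NA_real_, n, nrow(ped), dimnames = list(NULL, ped$id))
  fnd <- founders(ped)
  gt[, fnd] <- founder_dos[, fnd, drop = FALSE]
  for (i in ord) {
    if (ped$generation[i] == 0L) next
    fa <- ped$father[i]; mo <- ped$mother[i]
    from_f <- stats::rbinom(n, 1L, gt[, fa] / 2)
    from_m <- stats::rbinom(n, 1L, gt[, mo] / 2)
    gt[, ped$id[i]] <- from_f + from_m
  }
  gt
}

#' Gene-drop genotypes for one or more unlinked variants
#'
#' Founder genotypes are drawn binomially at the given allele frequency (or
#' a single heterozygous copy is placed in `origin`); each child then
#' inherits one allele from each parent uniformly at random (Mendel's law).
#' Variants are independent (no linkage).
#'
#' @param ped a [pedigree()]
#' @param freq founder allele frequency in `[0, 1]` (scalar or length-`n`)
#' @param n number of independent variants to drop (default 1)
#' @param origin optional founder id: instead of frequency draws, this
#'   founder is heterozygous and all other founders are homozygous reference
#' @param seed optional RNG seed
#' @return `n` x members dosage matrix (columns named by member id)
#' @export
gene_drop <- function(ped, freq = NULL, n = 1, origin = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fnd <- founders(ped)
  founder_dos <- matrix(0, n, nrow(ped), dimnames = list(NULL, ped$id))
  if (!is.null(origin)) {
    if (!origin %in% fnd) stop("origin must be a founder id")
    founder_dos[, origin] <- 1
  } else {
    stopifnot(!is.null(freq), all(freq >= 0 & freq <= 1))
    freq <- rep_len(freq, n)
    for (f in fnd) founder_dos[, f] <- stats::rbinom(n, 2L, freq)
  }
  gene_drop_core(ped, founder_dos[, , drop = FALSE])
}

# affected first-degree relative count per member
affected_first_degree <- function(ped) {
  aff <- ped$id[!is.na(ped$affected) & ped$affected]
  vapply(seq_len(nrow(ped)), function(i) {
    me <- ped$id[i]
    parents <- c(ped$father[i], ped$mother[i])
    children <- ped$id[!is.na(ped$father) & ped$father == me |
                         !is.na(ped$mother) & ped$mother == me]
    sibs <- ped$id[(!is.na(ped$father) & !is.na(ped$father[i]) &
                      ped$father == ped$father[i] |
                      !is.na(ped$mother) & !is.na(ped$mother[i]) &
                      ped$mother == ped$mother[i]) & ped$id != me]
    sum(unique(stats::na.omit(c(parents, children, sibs))) %in% aff)
  }, integer(1))
}

# status assignment from observable phenotype + age (never carrier truth)
assign_statuses <- function(ped, spec) {
  seq_ids <- if (identical(spec$sequencing_subset, "all")) ped$id
             else spec$sequencing_subset
  ped$sequenced <- ped$id %in% seq_ids
  afd <- affected_first_degree(ped)
  age <- spec$ref_year - ped$birth_year
  dx_age <- ped$diagnosis_year - ped$birth_year
  status <- rep("UNINFORMATIVE", nrow(ped))
  is_case <- ped$sequenced & !is.na(ped$affected) & ped$affected
  status[is_case] <- ifelse(!is.na(dx_age[is_case]) &
                              dx_age[is_case] >= spec$late_onset_age,
                            "CASE_POSSIBLE_PHENOCOPY", "CASE_DEFINITE")
  is_ctrl <- ped$sequenced & !is.na(ped$affected) & !ped$affected
  status[is_ctrl] <- ifelse(age[is_ctrl] < spec$young_control_age |
                              afd[is_ctrl] >= 3,
                            "CONTROL_POSSIBLE_CARRIER", "CONTROL_NONCARRIER")
  ped$status <- status
  validate_pedigree(ped)
}

#' Count informative meioses for a variant's transmission
#'
#' A meiosis is informative when a heterozygous carrier parent transmits (or
#' not) to a sequenced child whose status constrains the default segregation
#' policy (`CASE_DEFINITE` or `CONTROL_NONCARRIER`).
#'
#' @param ped a [pedigree()] with statuses assigned
#' @param gt named dosage vector over all members
#' @return integer count
#' @export
informative_meioses <- function(ped, gt) {
  constrained <- ped$sequenced &
    ped$status %in% c("CASE_DEFINITE", "CONTROL_NONCARRIER")
  k <- 0L
  for (i in which(constrained)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p) && !is.na(gt[p]) && gt[p] == 1) k <- k + 1L
    }
  }
  k
}

#' Inject the causal variant and derive phenotypes and statuses
#'
#' Gene-drops a single causal copy from the origin founder, assigns
#' affection (carriers affected with probability `causal_penetrance`,
#' non-carriers with probability `phenocopy_rate`), draws diagnosis ages for
#' the affected, and derives the five-level statuses from the observable
#' phenotype and age rules only.
#'
#' @param ped a [pedigree()] (e.g. from [simulate_pedigree()])
#' @param spec a [simulation_spec()]
#' @param origin founder carrying the mutation (default: first founder)
#' @param seed optional RNG seed
#' @return list with `ped` (statuses assigned), `gt` (named dosage vector
#'   over all members), `carriers` (ids) and `k_informative`
#' @export
inject_causal <- function(ped, spec = simulation_spec(), origin = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(origin)) origin <- founders(ped)[1L]
  gt <- gene_drop(ped, origin = origin, n = 1)[1L, ]
  carrier <- gt >= 1
  aff <- ifelse(carrier,
                stats::runif(length(gt)) < spec$causal_penetrance,
                stats::runif(length(gt)) < spec$phenocopy_rate)
  ped$affected <- aff
  dx <- rep(NA_integer_, nrow(ped))
  onset <- pmax(25, round(stats::rnorm(sum(aff), spec$onset_mean,
                                       spec$onset_sd)))
  dx[aff] <- ped$birth_year[aff] + onset
  # diagnoses cannot postdate the reference year
  dx[!is.na(dx)] <- pmin(dx[!is.na(dx)], spec$ref_year)
  ped$diagnosis_year <- dx
  ped <- assign_statuses(ped, spec)
  list(ped = ped, gt = gt, carriers = names(gt)[carrier],
       k_informative = informative_meioses(ped, gt))
}

#' Simulate annotation bundles
#'
#' Decoy scores are drawn from background distributions (including, when
#' `boundary_decoys` is set, a few values at exactly the documented strict
#' thresholds); the causal variant is drawn from the deleterious parameter
#' set: top-tier CADD, conserved, all four predictors deleterious, absent
#' from the frequency catalogues, in an intolerant gene.
#'
#' @param variants the cohort's variant data.frame (for regions and MAF
#'   coupling)
#' @param causal_index row index of the causal variant (`NA` for none)
#' @param maf_1kg,maf_exac catalogue frequencies decided by the genotype
#'   simulation (may be `NA`)
#' @param spec a [simulation_spec()]
#' @param seed optional RNG seed
#' @return annotation data.frame suitable for [variant_cohort()]
#' @export
simulate_annotations <- function(variants, causal_index, maf_1kg, maf_exac,
                                 spec = simulation_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(variants)
  ann <- empty_annotations(variants$variant_id)
  ann$maf_1kg <- maf_1kg
  ann$maf_exac <- maf_exac
  ann$cadd_phred <- stats::runif(n, spec$decoy_cadd_range[1],
                                 spec$decoy_cadd_range[2])
  ann$gerp <- stats::runif(n, -3, 6)
  ann$phastcons <- stats::runif(n)
  draw_call <- function() {
    r <- stats::runif(n)
    out <- rep("tolerated", n)
    out[r < spec$p_deleterious] <- "deleterious"
    out[r > 1 - spec$p_predictor_missing] <- NA
    out
  }
  for (k in PREDICTOR_KEYS) ann[[k]] <- draw_call()
  for (k in INTOLERANCE_KEYS) {
    v <- stats::runif(n, 0, 100)
    v[stats::runif(n) < 0.2] <- NA
    ann[[k]] <- v
  }
  rk <- sample(c(REGULOME_LEVELS, NA), n, replace = TRUE)
  ann$regulome_rank <- rk
  tags <- c("enhancer", "promoter", "TFBS", "eQTL", "DNase")
  ann$haploreg_flags <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1L, prob = c(0.5, 0.25, 0.15, 0.1))
    if (k == 0L) NA_character_
    else paste(sample(tags, k), collapse = "|")
  }, character(1))
  is_utr3 <- variants$region == "utr3"
  mirsvr <- rep(NA_real_, n)
  mirsvr[is_utr3] <- stats::rnorm(sum(is_utr3), -0.1, 0.3)
  ann$mirsvr <- mirsvr

  if (spec$boundary_decoys && n >= 8L) {
    slots <- setdiff(seq(n, by = -1L, length.out = min(6L, n - 1L)),
                     causal_index)
    bvals <- list(c("cadd_phred", 10), c("cadd_phred", 20),
                  c("cadd_phred", 30), c("maf_1kg", 0.001),
                  c("gerp", 2.0), c("mirsvr", -0.1))
    for (s in seq_along(slots)) {
      if (s > length(bvals)) break
      f <- bvals[[s]][[1]]
      ann[[f]][slots[s]] <- as.numeric(bvals[[s]][[2]])
      if (f == "gerp") ann$phastcons[slots[s]] <- 0.3
    }
  }

  if (!is.na(causal_index)) {
    i <- causal_index
    ann$maf_1kg[i] <- NA; ann$maf_exac[i] <- NA
    ann$cadd_phred[i] <- stats::runif(1, spec$causal_cadd_range[1],
                                      spec$causal_cadd_range[2])
    ann$gerp[i] <- stats::runif(1, 3, 6)
    ann$phastcons[i] <- stats::runif(1, 0.6, 1)
    for (k in PREDICTOR_KEYS) ann[[k]][i] <- "deleterious"
    for (k in INTOLERANCE_KEYS) ann[[k]][i] <- stats::runif(1, 1, 20)
    ann$mirsvr[i] <- NA
  }
  ann
}

#' Simulate a complete annotated cohort
#'
#' The end-to-end generator: pedigree, causal injection with ascertainment
#' (the causal drop is redrawn until the family has at least `min_cases`
#' sequenced cases and `min_informative_meioses` informative meioses, as a
#' family must before it enters sequencing), decoy gene-drops, annotation
#' scores, and per-sample read evidence with designed technical failures.
#'
#' @param spec a [simulation_spec()]
#' @param seed integer seed; the run is fully reproducible given the seed
#' @return object of class `simulated_cohort`: list with `cohort`
#'   (a [variant_cohort()] over the sequenced members), `ped`, `truth`
#'   (causal id/index, carrier ids, informative meioses, per-variant decoy
#'   founder frequencies) and `spec`
#' @export
simulate_cohort <- function(spec = simulation_spec(), seed = 1) {
  set.seed(seed)
  ped <- simulate_pedigree(spec)

  for (try in 1:200) {
    inj <- inject_causal(ped, spec)
    n_cases <- sum(inj$ped$sequenced & !is.na(inj$ped$affected) &
                     inj$ped$affected)
    if (n_cases >= spec$min_cases &&
        inj$k_informative >= spec$min_informative_meioses) break
    if (try == 200L)
      stop("could not ascertain a qualifying family; relax min_cases / ",
           "min_informative_meioses or enlarge the template")
  }
  ped <- inj$ped

  nd <- spec$n_decoys
  rare <- stats::runif(nd) < spec$p_rare
  fnd <- founders(ped)
  founder_dos <- matrix(0, nd, nrow(ped), dimnames = list(NULL, ped$id))
  freq <- rep(NA_real_, nd)
  if (any(rare)) {
    ofo <- sample(fnd, sum(rare), replace = TRUE)
    founder_dos[cbind(which(rare), match(ofo, ped$id))] <- 1
  }
  if (any(!rare)) {
    freq[!rare] <- stats::runif(sum(!rare), spec$common_freq_range[1],
                                spec$common_freq_range[2])
    for (f in fnd)
      founder_dos[!rare, f] <- stats::rbinom(sum(!rare), 2L, freq[!rare])
  }
  decoy_gt <- gene_drop_core(ped, founder_dos)

  # interleave causal at a random position
  causal_index <- sample.int(nd + 1L, 1L)
  gt_all <- rbind(decoy_gt[seq_len(causal_index - 1L), , drop = FALSE],
                  inj$gt,
                  decoy_gt[seq(causal_index, length.out = nd - causal_index + 1L),
                           , drop = FALSE])
  n <- nd + 1L

  # sites: one chromosome, increasing positions; mostly SNVs
  pos <- sort(sample.int(5e7, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  is_indel <- stats::runif(n) < spec$indel_rate
  is_indel[causal_index] <- FALSE
  ref[is_indel] <- paste0(ref[is_indel],
                          sample(bases, sum(is_indel), replace = TRUE))
  alt[is_indel] <- substr(ref[is_indel], 1L, 1L)
  vclass <- ifelse(is_indel, "INDEL", "SNV")
  region <- sample(REGION_LEVELS, n, replace = TRUE,
                   prob = c(0.25, 0.08, 0.02, 0.10, 0.25, 0.20, 0.08, 0.02))
  region[causal_index] <- "missense"
  vid <- variant_key("1", pos, ref, alt)

  # catalogue frequencies: rare decoys near-zero or novel, common decoys
  # track their founder frequency
  maf1 <- maf2 <- rep(NA_real_, n)
  didx <- setdiff(seq_len(n), causal_index)
  drare <- logical(n); drare[didx] <- rare
  dfreq <- rep(NA_real_, n); dfreq[didx] <- freq
  rsel <- which(drare)
  novel <- stats::runif(length(rsel)) < spec$p_novel
  maf1[rsel[!novel]] <- stats::runif(sum(!novel), 0, spec$rare_maf_max)
  maf2[rsel[!novel]] <- stats::runif(sum(!novel), 0, spec$rare_maf_max)
  csel <- which(!drare & !is.na(dfreq))
  jit <- function(x) pmin(0.99, pmax(0.001, x * stats::runif(length(x), 0.8, 1.2)))
  maf1[csel] <- jit(dfreq[csel])
  maf2[csel] <- jit(dfreq[csel])

  samples <- sequenced_members(ped)
  gt <- gt_all[, samples, drop = FALSE]
  rownames(gt) <- vid
  # missing-genotype injection on decoys only
  if (spec$missing_gt_rate > 0) {
    drop_mask <- matrix(stats::runif(n * length(samples)) <
                          spec$missing_gt_rate, n, length(samples))
    drop_mask[causal_index, ] <- FALSE
    gt[drop_mask] <- NA
  }

  qual <- stats::runif(n, 30, 80)
  filt <- rep("PASS", n)
  dp <- matrix(stats::rpois(n * length(samples), 35), n, length(samples),
               dimnames = list(vid, samples))
  carr <- !is.na(gt) & gt >= 1
  het <- carr & gt == 1
  ab <- matrix(0L, n, length(samples))
  ab[carr] <- stats::rbinom(sum(carr), dp[carr],
                            ifelse(het[carr], 0.5, 0.95))
  ab[carr] <- pmax(ab[carr], 2L)  # a called carrier has seen alt reads
  adf <- matrix(0L, n, length(samples))
  adf[carr] <- stats::rbinom(sum(carr), ab[carr], 0.5)
  adr <- ab - adf
  dp <- pmax(dp, ab)

  # designed technical failures on decoys
  dsel <- function(rate) {
    cand <- which(seq_len(n) != causal_index & stats::runif(n) < rate)
    cand
  }
  qf <- dsel(spec$qual_fail_rate)
  qual[qf] <- stats::runif(length(qf), 5, 20)
  df <- dsel(spec$depth_fail_rate)
  for (i in df) {
    ci <- which(carr[i, ])
    if (length(ci) > 0L) {
      j <- ci[1L]
      dp[i, j] <- sample(0:5, 1L)
      ab_ij <- min(ab[i, j], dp[i, j])
      adf[i, j] <- min(adf[i, j], ab_ij)
      adr[i, j] <- ab_ij - adf[i, j]
    }
  }
  sf <- dsel(spec$strand_fail_rate)
  sf <- sf[!is_indel[sf]]
  adf[sf, ] <- adf[sf, ] + adr[sf, ]
  adr[sf, ] <- 0L
  inf <- dsel(spec$indel_fail_rate)
  inf <- inf[is_indel[inf]]
  filt[inf] <- "badReads"
  # causal variant is technically clean
  qual[causal_index] <- stats::runif(1, 50, 80)
  ci <- which(carr[causal_index, ])
  dp[causal_index, ] <- pmax(dp[causal_index, ], 20L)
  ab_c <- stats::rbinom(length(ci), dp[causal_index, ci], 0.5)
  ab_c <- pmax(ab_c, 6L)
  adf[causal_index, ci] <- ceiling(ab_c / 2)
  adr[causal_index, ci] <- floor(ab_c / 2)
  dp[causal_index, ci] <- pmax(dp[causal_index, ci], ab_c)

  variants <- data.frame(variant_id = vid, chrom = "1", pos = pos, ref = ref,
                         alt = alt, vclass = vclass, region = region,
                         qual = qual, filter = filt, stringsAsFactors = FALSE)
  ann <- simulate_annotations(variants, causal_index, maf1, maf2, spec)
  cohort <- variant_cohort(variants, samples,
                           list(gt = gt, dp = dp, adf = adf, adr = adr), ann)
  structure(list(cohort = cohort, ped = ped,
                 truth = list(causal_id = vid[causal_index],
                              causal_index = causal_index,
                              carriers = inj$carriers,
                              k_informative = inj$k_informative,
                              decoy_rare = drare, decoy_freq = dfreq),
                 spec = spec),
            class = "simulated_cohort")
}
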