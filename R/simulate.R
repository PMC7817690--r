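# Synthetic TCGA-like cohort generator with recorded ground truth.
#
# The generator states a world, it does not fit one: background gene
# TPM is log-normal with per-gene location and scale drawn once per
# cohort; short-H2A paralogues are silent (sub-0.5 TPM dropout noise)
# except in a planted reactivated fraction of tumors, where their TPM
# is log-normal around the configured median and floored above the
# positive threshold; CTA and planted DE genes shift in reactivated
# samples; Psi is Beta-distributed around per-event baselines with a
# planted mean shift in reactivated samples; somatic mutations are
# sprinkled sparsely with one configurable recurrent hotspot.

#' Configuration for [simulate_cohort()]
#'
#' Defaults describe a modest pan-cancer screen: two cancer types of 60
#' tumors, 1000 genes of which 60 are CTAs and 10 carry a planted
#' 2-fold shift, three H2A.B paralogues silent in 90% of tumors and
#' expressed around a median of 3 TPM in the rest, 50 splicing events
#' per class with a +0.2 Psi shift planted in 20% of alternative
#' events, and a sparse mutation background with a recurrent E121Q
#' hotspot.
#'
#' @param n_cancer_types,samples_per_type cohort shape.
#' @param n_genes total genes (CTAs and DE genes are subsets).
#' @param n_cta_genes number of genes flagged CTA.
#' @param n_sh2a_paralogues 1--3 of H2AFB1/H2AFB2/H2AFB3.
#' @param reactivation_fraction per-tumor probability of sH2A
#'   reactivation.
#' @param reactivated_tpm_location log-normal median TPM of an
#'   expressed paralogue (default 3).
#' @param cta_effect_sd CTA log-expression shift, in units of each
#'   gene's own SD, applied in reactivated samples.
#' @param cta_affected_fraction fraction of CTA genes carrying the
#'   shift (default 0.5).
#' @param n_de_genes,de_fold_change non-CTA genes with a planted
#'   multiplicative shift in reactivated samples.
#' @param n_splice_events_per_class events simulated per class.
#' @param planted_dpsi Psi mean shift in reactivated samples.
#' @param planted_event_fraction fraction of events planted per class.
#' @param planted_classes classes receiving planted events (default:
#'   every alternative class; constitutive events are never planted
#'   unless listed).
#' @param psi_concentration Beta concentration kappa (default 20).
#' @param psi_missing_rate probability a Psi cell is missing.
#' @param mutation_rate per-sample, per-pool-gene mutation probability.
#' @param hotspot list with `genes`, `change`, `count`: the recurrent
#'   hotspot records added on top of the background.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_cancer_types = 2, samples_per_type = 60,
                          n_genes = 1000, n_cta_genes = 60,
                          n_sh2a_paralogues = 3,
                          reactivation_fraction = 0.1,
                          reactivated_tpm_location = 3,
                          cta_effect_sd = 1, cta_affected_fraction = 0.5,
                          n_de_genes = 10, de_fold_change = 2,
                          n_splice_events_per_class = 50,
                          planted_dpsi = 0.2, planted_event_fraction = 0.2,
                          planted_classes = setdiff(EVENT_CLASSES,
                                                    "constitutive"),
                          psi_concentration = 20, psi_missing_rate = 0.05,
                          mutation_rate = 0.01,
                          hotspot = list(genes = c("HIST1H2AB", "HIST1H2AC",
                                                   "HIST1H2AG"),
                                         change = "E121Q", count = 10),
                          seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_cancer_types >= 1, samples_per_type >= 1, n_genes >= 1,
              n_cta_genes >= 0, n_cta_genes + n_de_genes <= n_genes,
              n_sh2a_paralogues >= 1, n_sh2a_paralogues <= 3,
              reactivation_fraction >= 0, reactivation_fraction <= 1,
              reactivated_tpm_location > 0,
              cta_affected_fraction >= 0, cta_affected_fraction <= 1,
              n_splice_events_per_class >= 1,
              planted_dpsi >= -1, planted_dpsi <= 1,
              planted_event_fraction >= 0, planted_event_fraction <= 1,
              psi_concentration > 0,
              psi_missing_rate >= 0, psi_missing_rate < 1,
              mutation_rate >= 0, mutation_rate <= 1)
    stopifnot(all(planted_classes %in% EVENT_CLASSES))
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "CohortConfig")
}

# run expr with the RNG seeded, then restore the caller's RNG state
with_cohort_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# log-normal truncated below: silent paralogues must stay classifiable
rlnorm_floor <- function(n, meanlog, sdlog, floor) {
  out <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- out <= floor))
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  out
}

#' Simulate a TCGA-like cohort with known ground truth
#'
#' @param config a [cohort_config()].
#' @return List with `expr` (`ExpressionMatrix`), `samples`
#'   (`SampleTable`), `annotation` (`GeneAnnotation`), `psi`
#'   (`PsiTable`), `mutations` (`MutationTable`) and `ground_truth`
#'   (which samples, genes and events carry planted effects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  with_cohort_rng(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  paralogues <- SH2A_PARALOGUES[seq_len(cfg$n_sh2a_paralogues)]
  types <- sprintf("CT%02d", seq_len(cfg$n_cancer_types))
  sample_id <- as.vector(vapply(types, function(ct)
    sprintf("%s_S%03d", ct, seq_len(cfg$samples_per_type)),
    character(cfg$samples_per_type)))
  cancer_type <- rep(types, each = cfg$samples_per_type)
  n_samp <- length(sample_id)
  samples <- sample_table(sample_id, cancer_type, "tumor")

  # ---- planted reactivation -------------------------------------------------
  reactivated <- runif(n_samp) < cfg$reactivation_fraction
  # which paralogues an individual reactivated tumor expresses: most
  # express H2AFB1 alone; tumors expressing H2AFB2 nearly always also
  # express the near-identical H2AFB3
  pat <- matrix(FALSE, n_samp, length(paralogues),
                dimnames = list(sample_id, paralogues))
  for (i in which(reactivated)) {
    if (length(paralogues) >= 3) {
      u <- runif(1)
      pat[i, ] <- if (u < 0.5) c(TRUE, FALSE, FALSE)
        else if (u < 0.9) c(FALSE, TRUE, TRUE) else c(TRUE, TRUE, TRUE)
    } else pat[i, ] <- TRUE
  }

  # ---- expression matrix ----------------------------------------------------
  bg_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  cta_ids <- bg_ids[seq_len(cfg$n_cta_genes)]
  de_ids <- if (cfg$n_de_genes > 0)
    bg_ids[cfg$n_cta_genes + seq_len(cfg$n_de_genes)] else character()
  meanlog <- rnorm(cfg$n_genes, mean = log(10), sd = 1.2)
  sdlog <- runif(cfg$n_genes, 0.25, 0.5)
  vals <- matrix(rlnorm(cfg$n_genes * n_samp, meanlog, sdlog),
                 nrow = cfg$n_genes, ncol = n_samp,
                 dimnames = list(bg_ids, sample_id))
  cta_affected <- cta_ids[seq_len(floor(cfg$cta_affected_fraction *
                                        length(cta_ids)))]
  if (any(reactivated)) {
    ridx <- which(reactivated)
    for (g in cta_affected) {
      j <- match(g, bg_ids)
      vals[j, ridx] <- vals[j, ridx] * exp(cfg$cta_effect_sd * sdlog[j])
    }
    vals[de_ids, ridx] <- vals[de_ids, ridx] * cfg$de_fold_change
  }
  # short-H2A rows: dropout noise strictly below 0.5 TPM when silent,
  # log-normal floored above 1.6 TPM when expressed
  sh2a <- matrix(rbinom(length(paralogues) * n_samp, 1L, 0.3) *
                   runif(length(paralogues) * n_samp, 0, 0.45),
                 nrow = length(paralogues),
                 dimnames = list(paralogues, sample_id))
  n_on <- sum(pat)
  if (n_on > 0)
    sh2a[t(pat)] <- rlnorm_floor(n_on, log(cfg$reactivated_tpm_location),
                                 0.5, 1.6)
  expr <- expression_matrix(rbind(vals, sh2a))

  # ---- annotation -----------------------------------------------------------
  chroms <- c(paste0("chr", 1:22), "chrX")
  chr_of <- sample(chroms, cfg$n_genes, replace = TRUE,
                   prob = c(rep(1, 22), 0.8))
  gene_chr <- c(chr_of, rep("chrX", length(paralogues)))
  all_ids <- c(bg_ids, paralogues)
  start <- integer(length(all_ids))
  for (ch in unique(gene_chr)) {
    idx <- which(gene_chr == ch)
    start[idx] <- 1L + 100000L * (seq_along(idx) - 1L)
  }
  categories <- lapply(seq_along(all_ids), function(i) {
    id <- all_ids[i]
    cc <- "coding"
    if (id %in% cta_ids) cc <- c(cc, "CTA")
    if (id %in% paralogues) cc <- c(cc, "sH2A_paralogue")
    cc
  })
  annotation <- gene_annotation(
    all_ids, symbol = all_ids, chromosome = gene_chr,
    start = start, end = start + 9999L, strand = "+",
    categories = categories,
    paralogue = ifelse(all_ids %in% paralogues, all_ids, NA_character_))

  # ---- Psi table ------------------------------------------------------------
  nev <- cfg$n_splice_events_per_class
  event_id <- as.vector(vapply(EVENT_CLASSES, function(cl)
    sprintf("%s_%03d", cl, seq_len(nev)), character(nev)))
  event_class <- rep(EVENT_CLASSES, each = nev)
  n_planted <- floor(cfg$planted_event_fraction * nev)
  planted <- event_class %in% cfg$planted_classes &
    as.vector(vapply(EVENT_CLASSES, function(cl)
      seq_len(nev) <= n_planted, logical(nev)))
  dpsi <- cfg$planted_dpsi
  mu <- numeric(length(event_id))
  is_const <- event_class == "constitutive"
  mu[is_const] <- runif(sum(is_const), 0.90, 0.99)
  # baselines for plantable events keep mu + dpsi inside [0.05, 0.95]
  # so the realized mean shift equals the planted one
  lo <- 0.05 + max(0, -dpsi); hi <- 0.95 - max(0, dpsi)
  mu[!is_const & planted] <- runif(sum(!is_const & planted), lo, hi)
  mu[!is_const & !planted] <- runif(sum(!is_const & !planted), 0.05, 0.95)
  k <- cfg$psi_concentration
  psi_mat <- matrix(NA_real_, length(event_id), n_samp,
                    dimnames = list(event_id, sample_id))
  for (j in seq_len(n_samp)) {
    mu_j <- mu + ifelse(planted & reactivated[j], dpsi, 0)
    psi_mat[, j] <- rbeta(length(mu_j), mu_j * k, (1 - mu_j) * k)
  }
  if (cfg$psi_missing_rate > 0)
    psi_mat[runif(length(psi_mat)) < cfg$psi_missing_rate] <- NA_real_
  psi <- psi_table(event_id, event_class, psi_mat)

  # ---- mutations ------------------------------------------------------------
  pool <- c(cfg$hotspot$genes,
            paste0("HIST1H2B", LETTERS[1:6]), "EZH2", "CREBBP", "B2M")
  hits <- which(matrix(runif(n_samp * length(pool)) < cfg$mutation_rate,
                       n_samp, length(pool)), arr.ind = TRUE)
  aa <- .AA_ALPHABET
  bg_mut <- if (nrow(hits)) {
    ref <- sample(aa, nrow(hits), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1L), character(1))
    data.frame(sample_id = sample_id[hits[, 1L]],
               gene_symbol = pool[hits[, 2L]],
               protein_change = paste0(ref, sample(1:125, nrow(hits),
                                                   replace = TRUE), alt),
               cancer_type = cancer_type[hits[, 1L]],
               stringsAsFactors = FALSE)
  } else NULL
  hs <- if (cfg$hotspot$count > 0) {
    sidx <- sample(n_samp, cfg$hotspot$count, replace = cfg$hotspot$count > n_samp)
    data.frame(sample_id = sample_id[sidx],
               gene_symbol = sample(cfg$hotspot$genes, cfg$hotspot$count,
                                    replace = TRUE),
               protein_change = cfg$hotspot$change,
               cancer_type = cancer_type[sidx], stringsAsFactors = FALSE)
  } else NULL
  mut_df <- rbind(bg_mut, hs)
  mutations <- if (is.null(mut_df))
    mutation_table(character(), character(), character(), character())
  else mutation_table(mut_df$sample_id, mut_df$gene_symbol,
                      mut_df$protein_change, mut_df$cancer_type)

  ground_truth <- list(
    reactivated_samples = sample_id[reactivated],
    paralogue_pattern = pat,
    cta_genes = cta_ids, cta_affected = cta_affected,
    de_genes = de_ids, de_fold_change = cfg$de_fold_change,
    planted_events = event_id[planted], planted_dpsi = dpsi,
    hotspot = cfg$hotspot)

  list(expr = expr, samples = samples, annotation = annotation,
       psi = psi, mutations = mutations, ground_truth = ground_truth)
}
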