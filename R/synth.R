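#' Specification of a synthetic case/control cohort
#'
#' Captures the statistical world the pipeline assumes: two-group
#' compositional counts with a minority of differentially abundant OTUs,
#' log-normal baseline abundances, Dirichlet-multinomial overdispersion,
#' variable sequencing depth, a random phylogeny, demographic structure for
#' matching, and clinical indicators optionally coupled to planted OTUs.
#' Defaults mirror a single-centre discovery design of 30 cases vs 31
#' controls with 8 planted effects at 4-fold change among 200 OTUs.
#'
#' @param n_case,n_control group sizes (default 30 / 31).
#' @param n_otus total OTUs (default 200).
#' @param n_effect planted differential OTUs (default 8; half enriched,
#'   half depleted in cases).
#' @param fold_change multiplicative effect size (> 0, default 4).
#' @param depth_mean,depth_dispersion negative-binomial sequencing depth
#'   (mean 20000, size 10; floored at 1000 reads).
#' @param base_abundance_sigma SD of log baseline abundances (default 1.5).
#' @param theta Dirichlet concentration scale: per-sample compositions are
#'   Dirichlet(theta x mean proportions); smaller theta = more
#'   overdispersion (default 50).
#' @param batch_sigma SD of per-OTU multiplicative log-normal cohort
#'   offsets (default 0; used by [generate_multicohort]).
#' @param age_mean,age_sd,age_shift age distribution; cases are shifted by
#'   `age_shift` years (default +5) so matching has work to do.
#' @param sex_prob probability of sex = 1.
#' @param couplings list of couplings `list(indicator=, otu=, slope=,
#'   noise=)`; `otu` may be an OTU id or `"effectK"` referring to the K-th
#'   planted OTU. Default couples SCr to the first planted OTU with slope 1
#'   and noise SD 0.3.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_case = 30, n_control = 31, n_otus = 200,
                           n_effect = 8, fold_change = 4,
                           depth_mean = 20000, depth_dispersion = 10,
                           base_abundance_sigma = 1.5, theta = 50,
                           batch_sigma = 0, age_mean = 45, age_sd = 15,
                           age_shift = 5, sex_prob = 0.5,
                           couplings = list(list(indicator = "SCr",
                                                 otu = "effect1",
                                                 slope = 1, noise = 0.3))) {
  stopifnot(n_case >= 1, n_control >= 1, n_otus >= 2,
            n_effect >= 0, n_effect <= n_otus, fold_change > 0,
            depth_mean > 0, depth_dispersion > 0, theta > 0,
            base_abundance_sigma > 0, batch_sigma >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

synth_phyla <- function() {
  c(Firmicutes = 0.45, Bacteroidota = 0.25, Proteobacteria = 0.15,
    Actinobacteriota = 0.10, Verrucomicrobiota = 0.05)
}

# Dirichlet-multinomial counts for one group given mean abundances.
dm_counts <- function(n, means, spec) {
  p <- length(means)
  alpha <- spec$theta * means / sum(means)
  depth <- pmax(rnbinom(n, mu = spec$depth_mean,
                        size = spec$depth_dispersion), 1000)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    g <- rgamma(p, shape = alpha)
    while (sum(g) == 0) g <- rgamma(p, shape = alpha)
    out[i, ] <- rmultinom(1, depth[i], g / sum(g))
  }
  out
}

resolve_coupling_otu <- function(otu, effect_ids) {
  if (grepl("^effect[0-9]+$", otu)) {
    k <- as.integer(sub("effect", "", otu))
    if (k > length(effect_ids)) stop("coupling refers to effect", k,
                                     " but only ", length(effect_ids),
                                     " effects planted")
    effect_ids[k]
  } else otu
}

#' Generate one synthetic case/control cohort
#'
#' Draws baseline mean abundances log-normally, multiplies case means by
#' the fold change on the planted OTUs (half up, half down), samples
#' per-sample compositions from a Dirichlet and counts from a multinomial
#' at a per-sample depth, attaches a random bifurcating phylogeny with
#' exponential branch lengths, placeholder taxonomy, demographics and
#' clinical indicators (coupled ones are slope x log relative abundance of
#' their OTU plus Gaussian noise, shifted positive). Byte-identical output
#' for identical seeds.
#'
#' @param spec a [synthetic_spec].
#' @param seed integer seed.
#' @param cohort_id cohort label written into the metadata.
#' @param id_prefix sample-id prefix.
#' @param means optional list(control=, case=) of mean abundance vectors,
#'   used by [generate_multicohort] to share ground truth across cohorts.
#' @param effect_ids optional pre-chosen planted OTU ids (with `means`).
#' @return List of class `synthetic_cohort`: `table` ([otu_table]),
#'   `metadata` ([sample_metadata]), `tree` ([ape::phylo]), `taxonomy`
#'   ([taxonomy_map]) and `truth` (planted OTU ids, per-OTU fold change and
#'   direction, resolved couplings, seed).
#' @export
generate_cohort <- function(spec, seed = 1, cohort_id = "cohort1",
                            id_prefix = "S", means = NULL,
                            effect_ids = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_otus
  otu_ids <- sprintf("OTU%03d", seq_len(p))
  set.seed(derive_seed(seed, paste0("cohort.", cohort_id)))

  if (is.null(means)) {
    base <- exp(rnorm(p, 0, spec$base_abundance_sigma))
    # Plant effects among the abundant quartile: differential taxa are
    # community members, and OTUs below the screen's 0.5% abundance
    # criterion could never be recovered regardless of effect size.
    eligible <- which(base >= quantile(base, 0.75))
    eff_idx <- if (spec$n_effect > 0)
      sort(sample(eligible, min(spec$n_effect, length(eligible))))
    else integer(0)
    n_eff <- length(eff_idx)
    if (n_eff < spec$n_effect)
      warning("only ", n_eff, " abundant OTUs available for ",
              spec$n_effect, " requested effects")
    n_up <- ceiling(n_eff / 2)
    dir <- rep(c(1, -1), c(n_up, n_eff - n_up))
    case_means <- base
    case_means[eff_idx] <- base[eff_idx] * spec$fold_change^dir
    means <- list(control = base, case = case_means)
    effect_ids <- otu_ids[eff_idx]
    direction <- setNames(dir, effect_ids)
  } else {
    direction <- attr(effect_ids, "direction")
    effect_ids <- as.character(effect_ids)
  }

  counts <- rbind(dm_counts(spec$n_control, means$control, spec),
                  dm_counts(spec$n_case, means$case, spec))
  n <- spec$n_control + spec$n_case
  sample_ids <- sprintf("%s%s%02d", id_prefix, cohort_id, seq_len(n))
  dimnames(counts) <- list(sample_ids, otu_ids)
  tab <- otu_table(counts)
  group <- rep(c("control", "case"), c(spec$n_control, spec$n_case))

  tree <- ape::rtree(p, tip.label = sample(otu_ids))
  tree$edge.length <- rexp(nrow(tree$edge), rate = 10)

  phy <- sample(names(synth_phyla()), p, replace = TRUE,
                prob = synth_phyla())
  tax <- taxonomy_map(otu_ids, sprintf(
    "Bacteria;%s;Class%02d;Order%02d;Family%02d;Genus%03d",
    phy, seq_len(p) %% 20, seq_len(p) %% 30, seq_len(p) %% 50, seq_len(p)))

  age <- rnorm(n, spec$age_mean + spec$age_shift * (group == "case"),
               spec$age_sd)
  age <- pmin(pmax(age, 18), 90)
  sex <- rbinom(n, 1, spec$sex_prob)
  rel <- unclass(to_relative_abundance(tab))
  ind <- data.frame(ALB = pmax(rnorm(n, 35, 5), 5),
                    Pro24h = exp(rnorm(n, log(1.5), 0.6)),
                    SCr = pmax(rnorm(n, 70, 15), 20))
  couplings <- lapply(spec$couplings, function(cp) {
    cp$otu <- resolve_coupling_otu(cp$otu, effect_ids)
    cp
  })
  for (cp in couplings) {
    v <- cp$slope * log(rel[, cp$otu] + 1e-6) + rnorm(n, 0, cp$noise)
    ind[[cp$indicator]] <- v - min(v) + 0.1
  }

  meta <- sample_metadata(data.frame(
    sample_id = sample_ids, group = group, age = age, sex = sex,
    ALB = ind$ALB, Pro24h = ind$Pro24h, SCr = ind$SCr,
    cohort = cohort_id, stringsAsFactors = FALSE))

  structure(list(table = tab, metadata = meta, tree = tree, taxonomy = tax,
                 truth = list(effect_otus = effect_ids,
                              direction = direction,
                              fold_change = spec$fold_change,
                              couplings = couplings, seed = seed,
                              means = means)),
            class = "synthetic_cohort")
}

#' Generate several cohorts sharing one ground truth
#'
#' All cohorts share baseline means and planted effects; each non-primary
#' cohort additionally receives independent per-OTU multiplicative
#' log-normal batch offsets of scale `batch_sigma`, emulating
#' cross-regional external validation. Cohort 1 uses the spec's sample
#' sizes; later cohorts default to 10 cases + 10 controls unless `sizes`
#' says otherwise.
#'
#' @param spec a [synthetic_spec].
#' @param n_cohorts number of cohorts (>= 2).
#' @param batch_sigma batch-offset scale (overrides `spec$batch_sigma`).
#' @param seed integer seed.
#' @param sizes optional list of `c(n_case, n_control)` per cohort.
#' @param flip_effects adversarial flag: reverse effect directions in
#'   cohorts 2+ (external AUC should then collapse below 0.5).
#' @return List of `synthetic_cohort`s sharing `truth$effect_otus`.
#' @export
generate_multicohort <- function(spec, n_cohorts = 2,
                                 batch_sigma = spec$batch_sigma, seed = 1,
                                 sizes = NULL, flip_effects = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), n_cohorts >= 2)
  first <- generate_cohort(spec, seed = seed, cohort_id = "cohort1")
  means <- first$truth$means
  effect_ids <- first$truth$effect_otus
  attr(effect_ids, "direction") <- first$truth$direction
  out <- list(first)
  for (k in 2:n_cohorts) {
    sz <- if (!is.null(sizes) && length(sizes) >= k) sizes[[k]] else c(10, 10)
    spec_k <- spec
    spec_k$n_case <- sz[1]; spec_k$n_control <- sz[2]
    set.seed(derive_seed(seed, paste0("batch", k)))
    offset <- exp(rnorm(spec$n_otus, 0, batch_sigma))
    mk <- list(control = means$control * offset,
               case = means$case * offset)
    if (flip_effects) {
      idx <- match(effect_ids, sprintf("OTU%03d", seq_len(spec$n_otus)))
      ratio <- means$case[idx] / means$control[idx]
      mk$case[idx] <- mk$control[idx] / ratio # invert planted effects
    }
    ck <- generate_cohort(spec_k, seed = seed,
                          cohort_id = paste0("cohort", k),
                          means = mk, effect_ids = effect_ids)
    ck$truth$batch_offsets <- offset
    ck$truth$flipped <- flip_effects
    out[[k]] <- ck
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the same plain-text formats the readers consume: counts as TSV
#' (OTUs as rows), metadata as CSV, tree as newick, taxonomy as TSV and
#' ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  write_otu_table(cohort$table, paths["table"])
  write.csv(as.data.frame(cohort$metadata), paths["metadata"],
            row.names = FALSE)
  ape::write.tree(cohort$tree, paths["tree"])
  tx <- cohort$taxonomy
  lin <- apply(tx[, tax_ranks()], 1, function(r)
    paste(r[!is.na(r)], collapse = ";"))
  write.table(data.frame(otu_id = tx$otu_id, lineage = lin),
              paths["taxonomy"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  truth$means <- NULL # implementation detail, not ground truth
  writeLines(jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE),
             paths["truth"])
  invisible(paths)
}
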