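#' Configuration for a synthetic endurance-horse cohort
#'
#' Defines the generative model used by [generate_cohort()]: a cohort of
#' `n_samples` animals split between two latent gut community types, OTU
#' counts drawn Dirichlet-multinomial with community-specific parameter
#' vectors on a simulated phylogeny, and community-linked (diet, elimination,
#' SCFA, metabolite) plus community-independent (age, sex, breed) metadata.
#'
#' The defaults emulate the structure of a 51-horse endurance cohort: a 15/36
#' split between community types, race-elimination probabilities 0.33 vs
#' 0.16, identical age/sex/breed distributions across communities, higher
#' protein/fiber/ash intakes in community 2, acetate-dominated fecal SCFA in
#' community 1 versus higher propionate/butyrate in community 2, and a small
#' set of spectral bins (alanine/valine proxies) elevated in community 1.
#'
#' @param n_samples number of animals.
#' @param n_otus number of OTUs (tree tips).
#' @param n_genera number of genera; each genus owns a contiguous clade.
#' @param community_proportions probability vector over community types,
#'   must sum to 1.
#' @param effect_size non-negative scalar; Dirichlet parameters of
#'   discriminant genera are multiplied by `exp(+effect_size)` or
#'   `exp(-effect_size)` (alternating sign) in community 1.
#' @param n_discriminant_genera number of genera shifted between communities
#'   (default 30% of `n_genera`: 30 at the default size).
#' @param n_exclusive_genera number of genera present in only one community,
#'   alternately zeroed in community 2 and community 1 (default 10% of
#'   `n_genera`).
#' @param concentration total Dirichlet mass; smaller values give more
#'   overdispersed (subject-specific) compositions.
#' @param richness_thinning fraction of multi-OTU-genus tips silenced in
#'   community 1 (within-genus weights re-normalized, so genus-level expected
#'   profiles are unaffected); reproduces the reduced OTU richness of
#'   community 1.
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth parameters.
#' @param metadata_effects named list describing per-community metadata
#'   distributions; see [default_metadata_effects()].
#' @param scfa_alpha 2 x 6 matrix of Dirichlet parameters for the fecal SCFA
#'   proportions (acetate, propionate, butyrate, iso-butyrate, valerate,
#'   iso-valerate) of each community.
#' @param n_metabolite_bins number of NMR-style spectral bins.
#' @param metabolite_shift log-scale elevation of the designated
#'   alanine/valine proxy bins in community 1.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 51L,
                             n_otus = 200L,
                             n_genera = 100L,
                             community_proportions = c(15, 36) / 51,
                             effect_size = 3,
                             n_discriminant_genera = NULL,
                             n_exclusive_genera = NULL,
                             concentration = 200,
                             richness_thinning = 0.25,
                             depth_log_mean = log(5000),
                             depth_log_sd = 0.25,
                             metadata_effects = default_metadata_effects(),
                             scfa_alpha = default_scfa_alpha(),
                             n_metabolite_bins = 120L,
                             metabolite_shift = 0.8,
                             seed = 1L) {
  n_genera_chk <- check_scalar_count(n_genera, "n_genera")
  if (is.null(n_discriminant_genera)) { # default: 30% of genera shifted
    n_discriminant_genera <- max(1L, round(0.3 * n_genera_chk))
  }
  if (is.null(n_exclusive_genera)) { # default: 10% community-exclusive
    n_exclusive_genera <- round(0.1 * n_genera_chk)
  }
  cfg <- list(
    n_samples = check_scalar_count(n_samples, "n_samples"),
    n_otus = check_scalar_count(n_otus, "n_otus", min = 2L),
    n_genera = check_scalar_count(n_genera, "n_genera"),
    community_proportions = as.numeric(community_proportions),
    effect_size = as.numeric(effect_size),
    n_discriminant_genera = check_scalar_count(n_discriminant_genera,
                                               "n_discriminant_genera", 0L),
    n_exclusive_genera = check_scalar_count(n_exclusive_genera,
                                            "n_exclusive_genera", 0L),
    concentration = as.numeric(concentration),
    richness_thinning = check_probability(richness_thinning,
                                          "richness_thinning"),
    depth_log_mean = as.numeric(depth_log_mean),
    depth_log_sd = as.numeric(depth_log_sd),
    metadata_effects = metadata_effects,
    scfa_alpha = scfa_alpha,
    n_metabolite_bins = check_scalar_count(n_metabolite_bins,
                                           "n_metabolite_bins", 2L),
    metabolite_shift = as.numeric(metabolite_shift),
    seed = as.integer(seed)
  )
  if (abs(sum(cfg$community_proportions) - 1) > 1e-9) {
    stop_invalid("'community_proportions' must sum to 1")
  }
  if (length(cfg$community_proportions) != 2L) {
    stop_invalid("exactly two community types are supported")
  }
  if (any(cfg$community_proportions <= 0)) {
    stop_invalid("community proportions must be positive")
  }
  if (!is.finite(cfg$effect_size) || cfg$effect_size < 0) {
    stop_invalid("'effect_size' must be a non-negative scalar")
  }
  if (cfg$n_discriminant_genera + cfg$n_exclusive_genera > cfg$n_genera) {
    stop_invalid("n_discriminant_genera + n_exclusive_genera exceeds n_genera")
  }
  if (cfg$n_genera > cfg$n_otus) {
    stop_invalid("'n_genera' cannot exceed 'n_otus'")
  }
  if (cfg$concentration <= 0) stop_invalid("'concentration' must be positive")
  if (!is.matrix(cfg$scfa_alpha) || any(dim(cfg$scfa_alpha) != c(2L, 6L)) ||
      any(cfg$scfa_alpha <= 0)) {
    stop_invalid("'scfa_alpha' must be a positive 2 x 6 matrix")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default per-community metadata distributions
#'
#' Each element is `list(type, ...)` with `type` one of `"binary"`
#' (fields `p`: length-2 success probabilities), `"normal"` (`mean`, `sd`:
#' length-2 each, plus optional `floor`), or `"categorical"` (`levels`,
#' `prob`: a 2-row matrix of level probabilities). Index 1 refers to
#' community type 1. Age, sex and breed are identical across communities;
#' race elimination, race distance, speed, pulse and diet intakes differ.
#'
#' @return named list consumed by [synthetic_config()].
#' @export
default_metadata_effects <- function() {
  list(
    sex = list(type = "categorical",
               levels = c("female", "gelding", "male"),
               prob = rbind(c(0.40, 0.45, 0.15), c(0.40, 0.45, 0.15))),
    breed = list(type = "categorical",
                 levels = c("AR", "AA", "CS"),
                 prob = rbind(c(0.60, 0.25, 0.15), c(0.60, 0.25, 0.15))),
    age_years = list(type = "normal", mean = c(9.3, 9.3), sd = c(2.2, 2.2),
                     floor = 3),
    eliminated = list(type = "binary", p = c(0.33, 0.16)),
    ranking_category = list(type = "categorical",
                            levels = c("top25", "mid50", "last25"),
                            prob = rbind(c(0.25, 0.50, 0.25),
                                         c(0.25, 0.50, 0.25))),
    distance_km = list(type = "categorical",
                       levels = c("90", "120", "160"),
                       prob = rbind(c(0.15, 0.25, 0.60),
                                    c(0.45, 0.45, 0.10))),
    speed_kmh = list(type = "normal", mean = c(16.7, 17.2), sd = c(1.68, 1.60),
                     floor = 8),
    pulse_bpm = list(type = "normal", mean = c(56.1, 54.5), sd = c(3.6, 5.7),
                     floor = 30),
    protein_intake_kg = list(type = "normal", mean = c(0.55, 0.70),
                             sd = c(0.10, 0.10), floor = 0.1),
    fiber_intake_kg = list(type = "normal", mean = c(1.9, 2.3),
                           sd = c(0.30, 0.30), floor = 0.5),
    ash_intake_kg = list(type = "normal", mean = c(0.28, 0.35),
                         sd = c(0.05, 0.05), floor = 0.05),
    ufc_intake = list(type = "normal", mean = c(4.2, 4.6), sd = c(0.6, 0.6),
                      floor = 1),
    telomere_ratio = list(type = "normal", mean = c(1.0, 1.0),
                          sd = c(0.15, 0.15), floor = 0.2),
    travel_hours = list(type = "normal", mean = c(3, 3), sd = c(1.5, 1.5),
                        floor = 0),
    feces_ph = list(type = "normal", mean = c(6.6, 6.6), sd = c(0.3, 0.3),
                    floor = 5)
  )
}

#' @rdname default_metadata_effects
#' @export
default_scfa_alpha <- function() {
  a <- rbind(c(0.72, 0.14, 0.05, 0.03, 0.03, 0.03),
             c(0.64, 0.20, 0.09, 0.025, 0.025, 0.02)) * 150
  colnames(a) <- c("acetate", "propionate", "butyrate", "iso_butyrate",
                   "valerate", "iso_valerate")
  rownames(a) <- c("community_1", "community_2")
  a
}

#' Simulate a rooted binary phylogeny
#'
#' Random rooted binary tree with strictly positive branch lengths,
#' deterministic given the seed. Tips are labelled `otu_0001 ...`.
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::rtree()] `phylo` object.
#' @export
generate_tree <- function(n_otus, seed = 1L) {
  n_otus <- check_scalar_count(n_otus, "n_otus", min = 2L)
  with_local_seed(seed, {
    ape::rtree(n_otus, rooted = TRUE,
               tip.label = sprintf("otu_%04d", seq_len(n_otus)))
  })
}

# Tree with one contiguous clade per genus: a genus backbone tree whose tips
# are replaced (textually, via Newick) by within-genus subtrees with short
# branches, so genus-level abundance shifts dominate UniFrac.
genus_clade_tree <- function(otu_of_genus, subtree_scale = 0.1) {
  n_genera <- length(otu_of_genus)
  backbone <- ape::rtree(n_genera, rooted = TRUE,
                         tip.label = sprintf("g%04d", seq_len(n_genera)))
  if (n_genera == 1L) {
    nwk <- sprintf("(%s:1.0);", backbone$tip.label)
  } else {
    nwk <- ape::write.tree(backbone)
  }
  for (g in seq_len(n_genera)) {
    otus <- otu_of_genus[[g]]
    rep_nwk <- if (length(otus) == 1L) {
      otus
    } else if (length(otus) == 2L) {
      sprintf("(%s:%.6f,%s:%.6f)", otus[1], stats::runif(1) * subtree_scale,
              otus[2], stats::runif(1) * subtree_scale)
    } else {
      sub <- ape::rtree(length(otus), rooted = TRUE, tip.label = otus)
      sub$edge.length <- sub$edge.length * subtree_scale
      sub("\\);$", ")", ape::write.tree(sub))
    }
    nwk <- sub(sprintf("g%04d:", g), sprintf("%s:", rep_nwk), nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}

#' Generate a synthetic two-community cohort
#'
#' Draws a full cohort from a [synthetic_config()]: a genus-clade phylogeny,
#' Dirichlet-multinomial OTU counts with community-specific Dirichlet
#' parameters (shared base vector; discriminant genera multiplicatively
#' shifted by `exp(+/- effect_size)` in community 1; exclusive genera zeroed
#' in one community; community-1 OTU support thinned), log-normal sequencing
#' depths, metadata drawn per `metadata_effects`, Dirichlet SCFA proportions,
#' and a low-rank log-normal metabolite-bin matrix with designated
#' alanine/valine proxy bins elevated in community 1 and a random per-sample
#' dilution factor (so probabilistic-quotient normalization is meaningful).
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort` with elements `otu_table`
#'   ([otu_table]), `tree` (`phylo`), `true_labels` (named integer vector),
#'   `metadata` (data.frame), `scfa` (matrix, rows sum to 1),
#'   `metabolite_bins` (non-negative matrix), `genus_info` (data.frame of
#'   per-genus roles: discriminant sign, exclusivity), and `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 12, n_otus = 40,
#'                                            n_genera = 20, seed = 7))
#' table(cohort$true_labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    n1 <- max(1L, round(n * cfg$community_proportions[1]))
    n2 <- n - n1
    if (n2 < 1L) stop_invalid("community 2 is empty at this sample size")
    labels <- rep(c(1L, 2L), times = c(n1, n2))
    sample_id <- sprintf("horse_%03d", seq_len(n))
    names(labels) <- sample_id

    # --- taxonomy scaffold: OTUs per genus (every genus gets >= 1 OTU)
    G <- cfg$n_genera
    genus_of_otu <- sort(c(seq_len(G),
                           sample.int(G, cfg$n_otus - G, replace = TRUE)))
    otu_id <- sprintf("otu_%04d", seq_len(cfg$n_otus))
    otu_of_genus <- split(otu_id, genus_of_otu)
    genus_names <- sprintf("genus_%03d", seq_len(G))
    n_phyla <- 6L
    phylum_of_genus <- sprintf("phylum_%02d", sample.int(n_phyla, G,
                                                         replace = TRUE))
    family_of_genus <- sprintf("family_%03d", ceiling(seq_len(G) / 3))
    taxonomy <- data.frame(
      otu_id = otu_id,
      phylum = phylum_of_genus[genus_of_otu],
      class = paste0("class_", phylum_of_genus[genus_of_otu]),
      order = paste0("order_", family_of_genus[genus_of_otu]),
      family = family_of_genus[genus_of_otu],
      genus = genus_names[genus_of_otu],
      stringsAsFactors = FALSE
    )

    # --- phylogeny: one contiguous clade per genus
    tree <- genus_clade_tree(otu_of_genus)

    # --- community-specific Dirichlet parameters at genus level
    base_mass <- exp(stats::rnorm(G, 0, 1.2))
    base_alpha <- cfg$concentration * base_mass / sum(base_mass)
    roles <- sample.int(G) # random genus order for role assignment
    disc <- roles[seq_len(cfg$n_discriminant_genera)]
    excl <- roles[cfg$n_discriminant_genera +
                    seq_len(cfg$n_exclusive_genera)]
    disc_sign <- integer(G)
    if (length(disc)) {
      disc_sign[disc] <- rep_len(c(1L, -1L), length(disc))
    }
    exclusive_to <- integer(G) # 0 = shared, 1/2 = only in that community
    if (length(excl)) exclusive_to[excl] <- rep_len(c(1L, 2L), length(excl))

    alpha1_g <- base_alpha * exp(disc_sign * cfg$effect_size)
    alpha2_g <- base_alpha
    alpha1_g[exclusive_to == 2L] <- 0
    alpha2_g[exclusive_to == 1L] <- 0

    # --- spread genus mass over OTUs; thin community-1 OTU support
    w <- numeric(cfg$n_otus)
    for (g in seq_len(G)) {
      idx <- which(genus_of_otu == g)
      w[idx] <- rdirichlet1(rep(1, length(idx)))
    }
    keep1 <- rep(TRUE, cfg$n_otus)
    if (cfg$richness_thinning > 0) {
      multi <- which(tabulate(genus_of_otu)[genus_of_otu] > 1)
      drop <- sample(multi, size = floor(cfg$richness_thinning * length(multi)))
      # always retain at least one OTU per genus in community 1
      for (g in unique(genus_of_otu[drop])) {
        idx <- which(genus_of_otu == g)
        if (all(idx %in% drop)) drop <- setdiff(drop, idx[1])
      }
      keep1[drop] <- FALSE
    }
    w1 <- w * keep1
    for (g in seq_len(G)) { # re-normalize so genus-level means are preserved
      idx <- which(genus_of_otu == g)
      s <- sum(w1[idx])
      if (s > 0) w1[idx] <- w1[idx] / s
    }
    alpha_otu <- rbind(alpha1_g[genus_of_otu] * w1,
                       alpha2_g[genus_of_otu] * w)

    # --- Dirichlet-multinomial counts
    depth <- pmax(100L, as.integer(round(
      stats::rlnorm(n, cfg$depth_log_mean, cfg$depth_log_sd))))
    counts <- matrix(0L, n, cfg$n_otus, dimnames = list(sample_id, otu_id))
    for (i in seq_len(n)) {
      p_i <- rdirichlet1(alpha_otu[labels[i], ])
      counts[i, ] <- as.integer(stats::rmultinom(1, depth[i], p_i))
    }

    # --- metadata
    metadata <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
    metadata$stable <- sprintf("stable_%02d", sample.int(8L, n, replace = TRUE))
    metadata$trainer <- sprintf("trainer_%02d", sample.int(10L, n,
                                                           replace = TRUE))
    metadata$breeding <- sprintf("breeding_%02d", sample.int(6L, n,
                                                             replace = TRUE))
    for (v in names(cfg$metadata_effects)) {
      eff <- cfg$metadata_effects[[v]]
      metadata[[v]] <- switch(
        eff$type,
        binary = stats::rbinom(n, 1, eff$p[labels]) == 1,
        normal = {
          x <- stats::rnorm(n, eff$mean[labels], eff$sd[labels])
          if (!is.null(eff$floor)) x <- pmax(x, eff$floor)
          x
        },
        categorical = {
          vapply(seq_len(n), function(i) {
            sample(eff$levels, 1L, prob = eff$prob[labels[i], ])
          }, character(1))
        },
        stop_invalid("unknown metadata effect type: ", eff$type)
      )
    }

    # --- fecal SCFA proportions
    scfa <- t(vapply(seq_len(n),
                     function(i) rdirichlet1(cfg$scfa_alpha[labels[i], ]),
                     numeric(6)))
    dimnames(scfa) <- list(sample_id, colnames(cfg$scfa_alpha))

    # --- metabolite bins: low-rank signal + log-normal noise + dilution
    B <- cfg$n_metabolite_bins
    r <- 3L
    load <- matrix(stats::rnorm(B * r, 0, 0.5), B, r)
    scores <- matrix(stats::rnorm(n * r), n, r)
    mu <- stats::rnorm(B, 2, 0.5)
    logx <- sweep(scores %*% t(load), 2, mu, "+") +
      matrix(stats::rnorm(n * B, 0, 0.3), n, B)
    ala_bins <- seq(10L, min(14L, B))
    val_bins <- seq(min(30L, B - 4L), min(34L, B))
    shift_bins <- unique(c(ala_bins, val_bins))
    logx[labels == 1L, shift_bins] <- logx[labels == 1L, shift_bins] +
      cfg$metabolite_shift
    dilution <- stats::rlnorm(n, 0, 0.3)
    bins <- exp(logx) * dilution
    dimnames(bins) <- list(sample_id, sprintf("bin_%03d", seq_len(B)))
    attr(bins, "shifted_bins") <- colnames(bins)[shift_bins]

    cohort <- list(
      otu_table = otu_table(counts, taxonomy),
      tree = tree,
      true_labels = labels,
      metadata = metadata,
      scfa = scfa,
      metabolite_bins = bins,
      genus_info = data.frame(genus = genus_names,
                              phylum = phylum_of_genus,
                              discriminant_sign = disc_sign,
                              exclusive_to = exclusive_to,
                              base_alpha = base_alpha,
                              stringsAsFactors = FALSE),
      config = cfg
    )
    class(cohort) <- "synthetic_cohort"
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples (%s), %d OTUs, ",
                     "%d genera, seed %d\n"),
              length(x$true_labels),
              paste(table(x$true_labels), collapse = "/"),
              ncol(x$otu_table$counts),
              nrow(x$genus_info), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the OTU count table, taxonomy, Newick tree, metadata (with true
#' community labels), SCFA proportions and metabolite bins as TSV, and the
#' generating configuration as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_otu_table(cohort$otu_table, p("otu_counts.tsv"), p("taxonomy.tsv"))
  ape::write.tree(cohort$tree, p("tree.nwk"))
  md <- cbind(cohort$metadata,
              community_type = cohort$true_labels[cohort$metadata$sample_id])
  utils::write.table(md, p("metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cohort$scfa),
                                cohort$scfa, check.names = FALSE),
                     p("scfa.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cohort$metabolite_bins),
                                cohort$metabolite_bins, check.names = FALSE),
                     p("metabolite_bins.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- cohort$config
  cfg$metadata_effects <- NULL # nested defaults; re-create via synthetic_config
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
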