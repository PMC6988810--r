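#' Configuration for the synthetic community generator
#'
#' Emulates the sampling design of a two-habitat coastal survey: a
#' lagoon-like habitat A and a sea-like habitat B sampled at a few
#' stations on several dates with replicate filters, lognormal OTU
#' mean abundances (a few dominants over a long rare tail), unequal
#' lognormal library sizes, planted habitat specialists and
#' generalists, per-OTU seasonal preferences, and optional correlated
#' association blocks for network recovery tests.
#'
#' @param n_otus number of OTUs.
#' @param n_stations_A,n_stations_B stations per habitat (4 and 3 give
#'   the classic 7-station design).
#' @param n_dates sampling dates; `n_replicates` filters per event
#'   (4 dates x 2 replicates x 7 stations = 56 samples).
#' @param depth_mean,depth_dispersion lognormal library-size model
#'   (mean reads per sample and log-sd).
#' @param base_abundance_sigma lognormal sigma of OTU mean abundances.
#' @param habitat_effect fold-change (>= 1) of a specialist's expected
#'   abundance in its preferred habitat vs the other.
#' @param frac_specialist_A,frac_specialist_B,frac_generalist class
#'   proportions; the remainder is the rare tail.
#' @param rare_scale multiplier shrinking rare-class mean abundances.
#' @param season_effect fold-change (>= 1) on an OTU's preferred date.
#' @param association_blocks list of `list(habitat =, size =,
#'   strength =)` planting co-occurring OTU groups among the abundant
#'   specialists of that habitat; `strength` in [0, 1] is the share of
#'   a shared latent lognormal factor.
#' @param block_sigma log-sd of the latent block factor.
#' @param seed integer master seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_otus = 300L,
                             n_stations_A = 4L, n_stations_B = 3L,
                             n_dates = 4L, n_replicates = 2L,
                             depth_mean = 8000, depth_dispersion = 0.3,
                             base_abundance_sigma = 2,
                             habitat_effect = 8,
                             frac_specialist_A = 0.15,
                             frac_specialist_B = 0.15,
                             frac_generalist = 0.4,
                             rare_scale = 0.02,
                             season_effect = 3,
                             association_blocks = list(
                               list(habitat = "A", size = 8L, strength = 0.9),
                               list(habitat = "B", size = 8L, strength = 0.9)),
                             block_sigma = 1.5,
                             seed = 1L) {
  fr <- c(frac_specialist_A, frac_specialist_B, frac_generalist)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("class proportions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (habitat_effect < 1) stop("habitat_effect must be >= 1", call. = FALSE)
  if (season_effect < 1) stop("season_effect must be >= 1", call. = FALSE)
  stopifnot(n_otus >= 2, n_stations_A >= 1, n_stations_B >= 1,
            n_dates >= 1, n_replicates >= 1, depth_mean > 0)
  cfg <- list(n_otus = as.integer(n_otus),
              n_stations_A = as.integer(n_stations_A),
              n_stations_B = as.integer(n_stations_B),
              n_dates = as.integer(n_dates),
              n_replicates = as.integer(n_replicates),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              base_abundance_sigma = base_abundance_sigma,
              habitat_effect = habitat_effect,
              frac_specialist_A = frac_specialist_A,
              frac_specialist_B = frac_specialist_B,
              frac_generalist = frac_generalist,
              rare_scale = rare_scale,
              season_effect = season_effect,
              association_blocks = association_blocks,
              block_sigma = block_sigma,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

SYN_GROUPS <- data.frame(
  group = c("Bacillariophyta", "Dinophyceae", "Ciliophora", "Syndiniales",
            "Cryptophyceae", "Mamiellophyceae", "Chrysophyceae",
            "Dictyochophyceae", "Trebouxiophyceae", "MAST",
            "Labyrinthulea", "Oomycota", "Picozoa", "Cercozoa"),
  division = c("Ochrophyta", "Dinoflagellata", "Alveolata", "Dinoflagellata",
               "Cryptophyta", "Chlorophyta", "Ochrophyta", "Ochrophyta",
               "Chlorophyta", "Stramenopiles", "Stramenopiles",
               "Stramenopiles", "Picozoa", "Rhizaria"),
  stringsAsFactors = FALSE)

#' Generate a synthetic two-habitat OTU dataset with ground truth
#'
#' Per-sample counts are multinomial draws from expected relative
#' abundances built as: lognormal base mean x habitat preference
#' (specialists are `habitat_effect`-fold more abundant in their
#' habitat) x seasonal preference (`season_effect` on the OTU's
#' preferred date) x a shared latent lognormal factor within each
#' association block (shared per station-date event, so the signal
#' survives replicate pooling).  Library sizes are lognormal.  Fully
#' reproducible for a fixed `cfg$seed`.
#'
#' @param cfg a [synthetic_config].
#' @return list with `table` ([otu_table]), `metadata`
#'   ([sample_metadata]), `taxonomy` ([taxonomy_table]), and `truth`
#'   (data.frame: `otu_id`, `class`, `group`, `trophic`, `block`,
#'   `rel_A`, `rel_B` -- expected relative abundance in each habitat
#'   pool).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_otus
  ids <- sprintf("otu%04d", seq_len(n))

  n_sa <- round(cfg$frac_specialist_A * n)
  n_sb <- round(cfg$frac_specialist_B * n)
  n_ge <- round(cfg$frac_generalist * n)
  if (n_sa + n_sb + n_ge > n)
    stop("infeasible class proportions for n_otus", call. = FALSE)
  cls <- rep(c("specialist_A", "specialist_B", "generalist", "rare"),
             c(n_sa, n_sb, n_ge, n - n_sa - n_sb - n_ge))
  cls <- sample(cls)

  base <- exp(stats::rnorm(n, 0, cfg$base_abundance_sigma))
  base[cls == "rare"] <- base[cls == "rare"] * cfg$rare_scale

  # habitat weights: preferred habitat keeps the base mean, the other
  # is divided by the fold-change
  w_a <- base; w_b <- base
  w_b[cls == "specialist_A"] <- base[cls == "specialist_A"] / cfg$habitat_effect
  w_a[cls == "specialist_B"] <- base[cls == "specialist_B"] / cfg$habitat_effect

  pref_date <- sample.int(cfg$n_dates, n, replace = TRUE)

  # sampling design
  stations <- c(sprintf("StA%d", seq_len(cfg$n_stations_A)),
                sprintf("StB%d", seq_len(cfg$n_stations_B)))
  habitat_of <- rep(c("A", "B"), c(cfg$n_stations_A, cfg$n_stations_B))
  dates <- if (cfg$n_dates == 4L) c("Apr", "Jul", "Nov", "Feb")
           else sprintf("D%d", seq_len(cfg$n_dates))
  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        station = stations, date = dates,
                        stringsAsFactors = FALSE)
  design$habitat <- habitat_of[match(design$station, stations)]
  design$event <- paste(design$station, design$date, sep = "_")
  design$sample_id <- paste(design$event, design$replicate, sep = "_r")
  ns <- nrow(design)

  # association blocks among the most abundant specialists of the
  # block's habitat
  block_of <- rep(NA_integer_, n)
  blocks <- cfg$association_blocks
  if (length(blocks)) {
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      want <- if (identical(b$habitat, "A")) "specialist_A" else "specialist_B"
      cand <- which(cls == want & is.na(block_of))
      cand <- cand[order(base[cand], decreasing = TRUE)]
      if (length(cand) < b$size)
        stop("association block ", bi, " larger than the available ",
             want, " pool", call. = FALSE)
      block_of[cand[seq_len(b$size)]] <- bi
    }
  }

  # deterministic expected weights (OTU x sample), before latent noise
  season_mult <- matrix(1, n, ns)
  for (s in seq_len(ns)) {
    d_idx <- match(design$date[s], dates)
    season_mult[pref_date == d_idx, s] <- cfg$season_effect
  }
  hab_w <- ifelse(design$habitat == "A", 1, 0)
  W <- (w_a %o% hab_w) + (w_b %o% (1 - hab_w))
  W <- W * season_mult

  # latent block factors shared within a station-date event
  if (length(blocks)) {
    events <- unique(design$event)
    for (bi in seq_along(blocks)) {
      rho <- blocks[[bi]]$strength
      z_ev <- stats::rnorm(length(events))
      members <- which(block_of == bi)
      for (s in seq_len(ns)) {
        z <- z_ev[match(design$event[s], events)]
        eps <- stats::rnorm(length(members))
        W[members, s] <- W[members, s] *
          exp(cfg$block_sigma * (sqrt(rho) * z + sqrt(1 - rho) * eps))
      }
    }
  }

  depths <- pmax(100L, as.integer(round(stats::rlnorm(
    ns, log(cfg$depth_mean) - cfg$depth_dispersion^2 / 2,
    cfg$depth_dispersion))))
  counts <- matrix(0L, n, ns, dimnames = list(ids, design$sample_id))
  for (s in seq_len(ns))
    counts[, s] <- stats::rmultinom(1L, depths[s], W[, s] / sum(W[, s]))[, 1L]

  metadata <- sample_metadata(design[, c("sample_id", "station", "habitat",
                                         "date", "replicate")])

  # taxonomy consistent with the planted trophic structure: specialists
  # and generalists get groups cycling over the built-in pool
  grp <- SYN_GROUPS$group[(seq_len(n) - 1L) %% nrow(SYN_GROUPS) + 1L]
  lineage <- lapply(seq_len(n), function(i) {
    g <- grp[i]
    div <- SYN_GROUPS$division[SYN_GROUPS$group == g]
    c("Eukaryota", div, g, paste0(g, "_X"), paste0(g, "_XX"),
      paste0(g, "_fam", (i %% 7L) + 1L), paste0(g, "_gen", (i %% 13L) + 1L),
      paste0(g, "_sp", i))
  })
  taxonomy <- taxonomy_table(ids, lineage, group = grp)
  trophic <- assign_trophic(taxonomy)

  # expected relative abundance per habitat pool, marginal over the
  # latent factors (whose multiplier has a common mean within a block)
  Wdet <- ((w_a %o% hab_w) + (w_b %o% (1 - hab_w))) * season_mult
  rel_a <- rowSums(Wdet[, design$habitat == "A", drop = FALSE])
  rel_b <- rowSums(Wdet[, design$habitat == "B", drop = FALSE])
  truth <- data.frame(otu_id = ids, class = cls, group = grp,
                      trophic = unname(trophic[ids]), block = block_of,
                      rel_A = rel_a / sum(rel_a), rel_B = rel_b / sum(rel_b),
                      stringsAsFactors = FALSE)

  list(table = otu_table(counts), metadata = metadata,
       taxonomy = taxonomy, truth = truth, config = cfg)
}

#' Confusion table of planted vs CLAM classes
#'
#' Cross-tabulates the generator's planted class (with `rare` mapped
#' to the expectation `too_rare`) against the CLAM calls, and reports
#' per-class recall and the rate of specialist calls among planted
#' generalists.
#'
#' @param truth the `truth` data.frame from [generate_dataset()].
#' @param result a `clam_result`.
#' @return list with `table` (confusion matrix), `recall` (named per
#'   planted class), and `false_specialist_rate` (among planted
#'   generalists).
#' @export
truth_confusion <- function(truth, result) {
  common <- intersect(truth$otu_id, result$otu_id)
  if (length(common) == 0L)
    stop("truth and result share no OTU ids", call. = FALSE)
  tr <- truth[match(common, truth$otu_id), ]
  rs <- result[match(common, result$otu_id), ]
  planted <- factor(tr$class, levels = c("generalist", "specialist_A",
                                         "specialist_B", "rare"))
  called <- factor(as.character(rs$class),
                   levels = c("generalist", "specialist_A",
                              "specialist_B", "too_rare"))
  tab <- table(planted = planted, called = called)
  expected <- c(generalist = "generalist", specialist_A = "specialist_A",
                specialist_B = "specialist_B", rare = "too_rare")
  recall <- vapply(names(expected), function(p) {
    tot <- sum(tab[p, ])
    if (tot == 0) NA_real_ else tab[p, expected[[p]]] / tot
  }, numeric(1))
  gen <- planted == "generalist"
  fsr <- if (any(gen))
    mean(called[gen] %in% c("specialist_A", "specialist_B")) else NA_real_
  list(table = tab, recall = recall, false_specialist_rate = fsr)
}
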