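# Compositional community simulator: genus log-abundances respond linearly
# to a pH gradient, optionally share block latent factors (planted
# co-occurring guilds), and are observed through multinomial sequencing at
# realistic library depths.

#' Specify a synthetic community simulation
#'
#' Defaults emulate a seven-sample rhizosphere survey: ~700 genera across
#' ten phyla, library depths between 7,310 and 24,687 reads, and a soil pH
#' gradient from 3.84 to 7.79 with pH-responsive genera and two planted
#' blocks of co-occurring genera.
#'
#' @param n_samples number of samples along the gradient.
#' @param n_phyla number of phyla.
#' @param genera_per_phylum genera per phylum (total genera = product).
#' @param depth_range integer pair: min and max reads per sample.
#' @param ph_range numeric pair: min and max pH.
#' @param response_slope_sd sd of per-unit-pH log-abundance slopes.
#' @param block_specs list of `c(block_size, latent_sd)` pairs; each block is
#'   a set of genera sharing one latent factor per sample.
#' @param noise_sd sd of the residual log-abundance noise.
#' @param baseline_sd sd of genus baseline log-abundances (sets rank-abundance
#'   skew; 0 gives an even community).
#' @param ph_jitter sd of jitter added to the evenly spaced pH values (default
#'   0 so gradients are exactly reproducible).
#' @param concentration Dirichlet-multinomial concentration; `Inf` (default)
#'   gives plain multinomial sampling.
#' @param seed single integer; one global seed from which every stage derives
#'   its own sub-stream.
#' @return object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples = 7,
                            n_phyla = 10,
                            genera_per_phylum = 70,
                            depth_range = c(7310L, 24687L),
                            ph_range = c(3.84, 7.79),
                            response_slope_sd = 0.3,
                            block_specs = list(c(8, 1.5), c(8, 1.5)),
                            noise_sd = 0.5,
                            baseline_sd = 2,
                            ph_jitter = 0,
                            concentration = Inf,
                            seed = 1) {
  spec <- list(n_samples = n_samples, n_phyla = n_phyla,
               genera_per_phylum = genera_per_phylum,
               depth_range = depth_range, ph_range = ph_range,
               response_slope_sd = response_slope_sd,
               block_specs = block_specs, noise_sd = noise_sd,
               baseline_sd = baseline_sd, ph_jitter = ph_jitter,
               concentration = concentration, seed = seed)
  class(spec) <- "simulation_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    check_that(length(n_samples) == 1 && n_samples >= 2, "n_samples", "must be >= 2")
    check_that(length(n_phyla) == 1 && n_phyla >= 1, "n_phyla", "must be >= 1")
    check_that(length(genera_per_phylum) == 1 && genera_per_phylum >= 1,
               "genera_per_phylum", "must be >= 1")
    check_that(length(depth_range) == 2 && all(depth_range >= 1) &&
                 depth_range[1] <= depth_range[2], "depth_range",
               "must be an increasing pair of depths >= 1")
    check_that(length(ph_range) == 2 && ph_range[1] < ph_range[2], "ph_range",
               "min must be below max")
    check_that(response_slope_sd >= 0, "response_slope_sd", "must be >= 0")
    check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
    check_that(baseline_sd >= 0, "baseline_sd", "must be >= 0")
    check_that(ph_jitter >= 0, "ph_jitter", "must be >= 0")
    check_that(is.list(block_specs), "block_specs", "must be a list")
    for (b in block_specs) {
      check_that(length(b) == 2 && b[1] >= 1 && b[1] == round(b[1]) && b[2] >= 0,
                 "block_specs", "each entry must be c(block_size >= 1, latent_sd >= 0)")
    }
    n_genera <- n_phyla * genera_per_phylum
    blocked <- sum(vapply(block_specs, `[`, numeric(1), 1))
    check_that(n_genera >= blocked, "block_specs",
               sprintf("block sizes (%d) exceed total genera (%d)", blocked, n_genera))
    check_that(concentration > 0, "concentration", "must be > 0 (Inf = multinomial)")
  })
  as_seed(spec$seed, "seed")
  invisible(spec)
}

#' Generate a taxonomy map for a simulation
#'
#' Assigns each genus to exactly one phylum (and a matching class), with
#' unique names. Deterministic for a fixed spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return taxonomy data.frame (taxon, phylum, class, genus).
#' @export
generate_taxonomy <- function(spec) {
  validate_spec(spec)
  phyla <- sprintf("Phylum%02d", seq_len(spec$n_phyla))
  genera <- sprintf("g%03d_%s", seq_len(spec$n_phyla * spec$genera_per_phylum),
                    rep(phyla, each = spec$genera_per_phylum))
  data.frame(taxon = genera,
             phylum = rep(phyla, each = spec$genera_per_phylum),
             class = rep(sub("Phylum", "Class", phyla), each = spec$genera_per_phylum),
             genus = genera,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genus-by-sample count table
#'
#' Samples sit on an evenly spaced pH gradient. Each genus's latent
#' log-abundance is `baseline + slope * pH + block factor + noise`; per-sample
#' proportions are the softmax of the latent values and counts are drawn by
#' multinomial sampling at a depth uniform in `depth_range`. Column sums
#' therefore equal the drawn depths exactly.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `counts` (genus x sample integer matrix), `env`
#'   (environment table with correlated soil covariates), `taxonomy`, and
#'   `truth` (block membership, slopes, block latent factors, latent
#'   log-abundance matrix).
#' @export
generate_community <- function(spec) {
  validate_spec(spec)
  taxonomy <- generate_taxonomy(spec)
  genera <- taxonomy$taxon
  n_g <- length(genera)
  n_s <- spec$n_samples
  samples <- sprintf("S%02d", seq_len(n_s))

  ph <- seq(spec$ph_range[1], spec$ph_range[2], length.out = n_s)
  if (spec$ph_jitter > 0) {
    ph <- with_seed(stage_seed(spec$seed, "ph"), ph + stats::rnorm(n_s, 0, spec$ph_jitter))
    ph <- pmin(pmax(ph, 0.01), 13.99)
  }

  baseline <- with_seed(stage_seed(spec$seed, "baseline"),
                        stats::rnorm(n_g, 0, spec$baseline_sd))
  slopes <- with_seed(stage_seed(spec$seed, "slopes"),
                      stats::rnorm(n_g, 0, spec$response_slope_sd))
  names(slopes) <- genera

  # Assign blocks to disjoint random genera; each block contributes one
  # shared latent factor per sample to all its members.
  membership <- rep(NA_integer_, n_g)
  names(membership) <- genera
  n_blocks <- length(spec$block_specs)
  latent <- matrix(0, nrow = max(n_blocks, 0), ncol = n_s,
                   dimnames = if (n_blocks) list(paste0("block", seq_len(n_blocks)), samples))
  if (n_blocks > 0) {
    sizes <- vapply(spec$block_specs, `[`, numeric(1), 1)
    picked <- with_seed(stage_seed(spec$seed, "blocks"), sample(n_g, sum(sizes)))
    idx <- split(picked, rep(seq_len(n_blocks), sizes))
    latent_draw <- with_seed(stage_seed(spec$seed, "latent"),
                             stats::rnorm(n_blocks * n_s))
    for (b in seq_len(n_blocks)) {
      membership[idx[[b]]] <- b
      latent[b, ] <- latent_draw[seq((b - 1) * n_s + 1, b * n_s)] * spec$block_specs[[b]][2]
    }
  }

  eta <- outer(baseline, rep(1, n_s)) + outer(slopes, ph)
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      eta[which(membership == b), ] <- sweep(eta[which(membership == b), , drop = FALSE],
                                             2, latent[b, ], `+`)
    }
  }
  if (spec$noise_sd > 0) {
    eta <- eta + with_seed(stage_seed(spec$seed, "noise"),
                           matrix(stats::rnorm(n_g * n_s, 0, spec$noise_sd), n_g, n_s))
  }
  dimnames(eta) <- list(genera, samples)

  depths <- with_seed(stage_seed(spec$seed, "depths"),
                      sample(seq(spec$depth_range[1], spec$depth_range[2]), n_s,
                             replace = TRUE))
  counts <- with_seed(stage_seed(spec$seed, "counts"), {
    out <- matrix(0L, n_g, n_s, dimnames = list(genera, samples))
    for (s in seq_len(n_s)) {
      p <- softmax(eta[, s])
      if (is.finite(spec$concentration)) {
        # Dirichlet-multinomial overdispersion via a gamma-perturbed simplex.
        g <- stats::rgamma(n_g, shape = p * spec$concentration)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      out[, s] <- stats::rmultinom(1, depths[s], p)[, 1]
    }
    out
  })

  env <- with_seed(stage_seed(spec$seed, "env"), synth_env(samples, ph))

  truth <- list(block_membership = membership, slopes = slopes,
                latent_factors = latent, eta = eta, depths = depths)
  list(counts = counts, env = env, taxonomy = taxonomy, truth = truth)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Soil covariates with the survey's broad trends: NH4 and AP/NO3 move with /
# against pH; SOC, TP and texture are uncorrelated noise around field-typical
# values.
synth_env <- function(samples, ph) {
  n <- length(samples)
  z <- (ph - mean(ph)) / max(stats::sd(ph), 1e-9)
  env <- data.frame(
    sample = samples,
    pH = ph,
    SOC = pmax(stats::rnorm(n, 26, 5), 0.1),
    AP = pmax(0.28 - 0.08 * z + stats::rnorm(n, 0, 0.03), 0.01),
    TP = pmax(23 - 6 * z + stats::rnorm(n, 0, 3), 0.1),
    NO3 = pmax(6 - 3 * z + stats::rnorm(n, 0, 0.8), 0.01),
    NH4 = pmax(6.9 + 2.6 * z + stats::rnorm(n, 0, 0.5), 0.01),
    sand = pmax(stats::rnorm(n, 55, 6), 1),
    silt = pmax(stats::rnorm(n, 540, 20), 1),
    clay = pmax(stats::rnorm(n, 400, 20), 1),
    stringsAsFactors = FALSE
  )
  validate_env_table(env)
  env
}

#' Write all simulator outputs as TSV
#'
#' @param sim result of [generate_community()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             env = file.path(dir, "env.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(sim$counts, paths["counts"])
  write_env_table(sim$env, paths["env"])
  write_taxonomy(sim$taxonomy, paths["taxonomy"])
  truth_df <- data.frame(taxon = names(sim$truth$slopes),
                         block = ifelse(is.na(sim$truth$block_membership), "none",
                                        sim$truth$block_membership),
                         slope = sim$truth$slopes,
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
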