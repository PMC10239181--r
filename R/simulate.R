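#' Simulation configuration for synthetic WGBS count data
#'
#' Bundles every parameter of the strand-resolved count generator. The
#' defaults emulate the study design the package targets: 9 cases vs 4
#' controls, a merged per-CpG read depth around 36 (18 per strand), dense
#' CpG runs separated by gaps wide enough to trigger the 200 bp region
#' partition, mild beta-binomial over-dispersion, and sporadic missing
#' strand records.
#'
#' @param n_cases,n_controls number of case / control samples (each >= 1).
#' @param age_range numeric length-2, min and max age in years; ages are
#'   drawn uniformly on this interval.
#' @param chrom_layout list of chromosome descriptions, each a list with
#'   elements `chrom` (label), `cpgs` (integer vector: CpG count per
#'   intended region), `spacing` (length-2 integer range of within-region
#'   consecutive CpG spacings, bp) and `gap` (bp inserted between
#'   consecutive intended regions; must exceed `max(spacing)`).
#' @param depth_mean mean sequencing depth per strand (reads).
#' @param depth_dispersion negative-binomial dispersion of per-strand depth
#'   (0 gives Poisson depth).
#' @param overdispersion_rho intra-CpG read correlation in `[0, 1)`;
#'   methylated counts are beta-binomial with this intra-class correlation.
#' @param error_p0 probability an unmethylated cytosine read is observed
#'   methylated (incomplete conversion); `error_p1` the probability a
#'   methylated read is observed methylated. Require
#'   `0 <= error_p0 < error_p1 <= 1`.
#' @param error_p1 see `error_p0`.
#' @param missing_rate probability a sample x CpG x strand record is
#'   dropped from the output.
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 9L, n_controls = 4L,
                       age_range = c(20, 80),
                       chrom_layout = list(list(chrom = "chr1",
                                                cpgs = c(80L, 80L),
                                                spacing = c(2L, 50L),
                                                gap = 500L)),
                       depth_mean = 18, depth_dispersion = 0.3,
                       overdispersion_rho = 0.05,
                       error_p0 = 0, error_p1 = 1,
                       missing_rate = 0.05, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L,
            length(age_range) == 2L, age_range[1] <= age_range[2],
            depth_mean > 0, depth_dispersion >= 0,
            overdispersion_rho >= 0, overdispersion_rho < 1,
            error_p0 >= 0, error_p0 < error_p1, error_p1 <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (length(chrom_layout) == 0L) stop("no regions requested")
  for (cl in chrom_layout) {
    stopifnot(is.character(cl$chrom), length(cl$cpgs) >= 1L, all(cl$cpgs >= 1L),
              length(cl$spacing) == 2L, cl$spacing[1] >= 1L,
              cl$spacing[1] <= cl$spacing[2])
    if (cl$spacing[2] >= cl$gap)
      stop("within-region spacing max must be smaller than the between-region gap")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 age_range = age_range, chrom_layout = chrom_layout,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 overdispersion_rho = overdispersion_rho,
                 error_p0 = error_p0, error_p1 = error_p1,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate an expression with a temporary RNG state derived from `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  force(seed)  # force before snapshotting state: seed may itself draw RNG
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-stream seed derivation: distinct streams for positions, metadata and
# each sample so that adding samples never perturbs earlier samples' draws.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483629) + 1L
}

#' Simulate CpG positions with an intended region structure
#'
#' Lays out CpG sites chromosome by chromosome: consecutive CpGs inside an
#' intended region are separated by uniformly drawn spacings below the
#' partition gap, and consecutive intended regions by at least the
#' configured gap, so the 200 bp partition recovers the layout exactly.
#'
#' @param config a [sim_config()].
#' @return `data.table` with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within chromosome) and `region` (intended region label).
#' @export
simulate_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$chrom_layout) == 0L) stop("no regions requested")
  with_seed(derive_seed(config$seed, 1L), {
    out <- lapply(config$chrom_layout, function(cl) {
      pos_all <- integer(0); reg_all <- character(0)
      cur <- 1000L
      for (r in seq_along(cl$cpgs)) {
        n <- cl$cpgs[r]
        gaps <- if (n > 1L)
          sample(seq.int(cl$spacing[1], cl$spacing[2]), n - 1L, replace = TRUE)
        else integer(0)
        pos <- cur + c(0L, cumsum(gaps))
        pos_all <- c(pos_all, pos)
        reg_all <- c(reg_all, rep(sprintf("%s_r%d", cl$chrom, r), n))
        cur <- pos[n] + as.integer(cl$gap)
      }
      data.table::data.table(chrom = cl$chrom, pos = pos_all, region = reg_all)
    })
    data.table::rbindlist(out)
  })
}

#' Simulate sample metadata
#'
#' @param config a [sim_config()].
#' @return `data.table` with `sample_id`, `group` (`case`/`control`) and
#'   `age` (years, uniform over `config$age_range`).
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  ids <- c(sprintf("case%02d", seq_len(config$n_cases)),
           sprintf("ctrl%02d", seq_len(config$n_controls)))
  ages <- with_seed(derive_seed(config$seed, 2L),
                    round(stats::runif(n, config$age_range[1],
                                       config$age_range[2]), 1))
  data.table::data.table(sample_id = ids,
                         group = rep(c("case", "control"),
                                     c(config$n_cases, config$n_controls)),
                         age = ages)
}

#' Construct ground-truth smooth effect curves
#'
#' Builds the per-CpG logit-scale truth used by the generator: a baseline
#' curve, a disease effect curve and an age effect curve (per year). Each
#' argument may be a scalar (constant curve), a numeric vector aligned to
#' `positions`, or a function of the relative position `u` within the CpG's
#' intended region (`u` in `[0, 1]`), evaluated region by region.
#'
#' @param positions output of [simulate_positions()].
#' @param beta0,beta_disease,beta_age scalar, vector, or `function(u)`.
#' @return `data.table` with `chrom`, `pos`, `region`, `beta0`,
#'   `beta_disease`, `beta_age`.
#' @export
make_true_effects <- function(positions, beta0 = -0.5, beta_disease = 0,
                              beta_age = 0) {
  stopifnot(all(c("chrom", "pos", "region") %in% names(positions)))
  eval_curve <- function(spec) {
    if (is.function(spec)) {
      u <- numeric(nrow(positions))
      for (rg in unique(positions$region)) {
        idx <- which(positions$region == rg)
        p <- positions$pos[idx]
        u[idx] <- if (length(p) > 1L) (p - p[1]) / (p[length(p)] - p[1]) else 0.5
      }
      v <- spec(u)
      stopifnot(length(v) == nrow(positions))
      v
    } else if (length(spec) == 1L) {
      rep(as.numeric(spec), nrow(positions))
    } else {
      stopifnot(length(spec) == nrow(positions))
      as.numeric(spec)
    }
  }
  eff <- data.table::data.table(chrom = positions$chrom, pos = positions$pos,
                                region = positions$region,
                                beta0 = eval_curve(beta0),
                                beta_disease = eval_curve(beta_disease),
                                beta_age = eval_curve(beta_age))
  if (!all(is.finite(as.matrix(eff[, c("beta0", "beta_disease", "beta_age")]))))
    stop("effect curves must be finite")
  eff
}

#' A smooth bump curve for disease effects
#'
#' Convenience factory returning a Gaussian-shaped function of relative
#' region position, peaking at `height` in the region centre. Useful as the
#' `beta_disease` argument of [make_true_effects()].
#'
#' @param height peak logit-scale effect.
#' @param center,width bump centre and width on the relative `[0, 1]` scale.
#' @return a function of `u`.
#' @export
smooth_bump <- function(height, center = 0.5, width = 0.18) {
  force(height); force(center); force(width)
  function(u) height * exp(-0.5 * ((u - center) / width)^2)
}

# Beta-binomial draw with intra-class correlation rho; rho = 0 is binomial.
rbetabinom <- function(n_draws, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n_draws, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p_lat <- stats::rbeta(n_draws, a, b)
  # guard exact 0/1 probabilities where rbeta degenerates
  p_lat[prob <= 0] <- 0; p_lat[prob >= 1] <- 1
  stats::rbinom(n_draws, size, p_lat)
}

#' Simulate strand-resolved methylation counts
#'
#' For sample i at CpG t the true methylation probability is
#' `plogis(beta0(t) + D_i * beta_disease(t) + age_i * beta_age(t))` with
#' `D_i = 1` for cases. A per-(sample, CpG) latent probability drawn from a
#' Beta distribution with intra-class correlation `overdispersion_rho`
#' induces over-dispersion; the read-level error layer maps the latent
#' probability p to `p * error_p1 + (1 - p) * error_p0`; per-strand total
#' depths follow a negative-binomial with mean `depth_mean`; records are
#' dropped independently with `missing_rate`. Ages enter uncentered, on the
#' year scale.
#'
#' @param positions output of [simulate_positions()].
#' @param sample_meta output of [simulate_metadata()] (or a compatible
#'   table with `sample_id`, `group`, `age`).
#' @param effects output of [make_true_effects()], aligned to `positions`.
#' @param config the [sim_config()] used for `positions`.
#' @return `data.table` in the StrandCounts dialect: `chrom`, `pos`,
#'   `strand` (`+`/`-`; `pos` is the forward-strand C coordinate for both
#'   rows), `sample_id`, `meth`, `total`.
#' @export
simulate_counts <- function(positions, sample_meta, effects, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(effects) != nrow(positions) ||
      !all(effects$pos == positions$pos & effects$chrom == positions$chrom))
    stop("effects are not aligned to positions")
  if (config$depth_mean <= 0 || config$depth_dispersion < 0)
    stop("negative depth parameters")
  stopifnot(all(c("sample_id", "group", "age") %in% names(sample_meta)))
  n_cpg <- nrow(positions)
  rho <- config$overdispersion_rho
  out <- vector("list", nrow(sample_meta))
  for (i in seq_len(nrow(sample_meta))) {
    D <- as.integer(sample_meta$group[i] == "case")
    age <- sample_meta$age[i]
    eta <- effects$beta0 + D * effects$beta_disease + age * effects$beta_age
    pi_true <- stats::plogis(eta)
    out[[i]] <- with_seed(derive_seed(config$seed, 100L + i), {
      tot_f <- if (config$depth_dispersion > 0)
        stats::rnbinom(n_cpg, mu = config$depth_mean,
                       size = 1 / config$depth_dispersion)
      else stats::rpois(n_cpg, config$depth_mean)
      tot_r <- if (config$depth_dispersion > 0)
        stats::rnbinom(n_cpg, mu = config$depth_mean,
                       size = 1 / config$depth_dispersion)
      else stats::rpois(n_cpg, config$depth_mean)
      # latent per-CpG methylation prob (shared by both strands), then the
      # read-level error layer, then binomial per strand
      p_lat <- if (rho > 0) {
        a <- pi_true * (1 - rho) / rho
        b <- (1 - pi_true) * (1 - rho) / rho
        pl <- stats::rbeta(n_cpg, a, b)
        pl[pi_true <= 0] <- 0; pl[pi_true >= 1] <- 1
        pl
      } else pi_true
      p_obs <- p_lat * config$error_p1 + (1 - p_lat) * config$error_p0
      meth_f <- stats::rbinom(n_cpg, tot_f, p_obs)
      meth_r <- stats::rbinom(n_cpg, tot_r, p_obs)
      keep_f <- stats::runif(n_cpg) >= config$missing_rate
      keep_r <- stats::runif(n_cpg) >= config$missing_rate
      dt <- data.table::data.table(
        chrom = rep(positions$chrom, 2L),
        pos = rep(positions$pos, 2L),
        strand = rep(c("+", "-"), each = n_cpg),
        sample_id = sample_meta$sample_id[i],
        meth = c(meth_f, meth_r),
        total = c(tot_f, tot_r))
      dt[c(keep_f, keep_r)]
    })
  }
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("chrom", "pos", "sample_id", "strand"))
  res[]
}

#' Write / read the StrandCounts TSV dialect
#'
#' Tab-separated with header `chrom pos strand sample_id meth total`.
#' `read_counts` validates every row and reports malformed rows with their
#' file line numbers.
#'
#' @param x StrandCounts table.
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` the
#'   validated `data.table`.
#' @export
write_counts <- function(x, path) {
  cols <- c("chrom", "pos", "strand", "sample_id", "meth", "total")
  stopifnot(all(cols %in% names(x)))
  data.table::fwrite(x[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("chrom", "strand", "sample_id"),
    integer = c("pos", "meth", "total")))
  cols <- c("chrom", "pos", "strand", "sample_id", "meth", "total")
  if (!identical(names(x), cols))
    stop("malformed counts file: expected columns ", paste(cols, collapse = " "))
  if (nrow(x) == 0L) return(x)
  bad_strand <- which(!x$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("unknown strand symbol at line ", bad_strand[1] + 1L,
         " of ", path)
  bad_count <- which(x$meth > x$total | x$meth < 0L | x$total < 0L)
  if (length(bad_count))
    stop("methylated count exceeds total (or negative) at line ",
         bad_count[1] + 1L, " of ", path)
  x
}

#' Write / read sample metadata TSV (`sample_id group age`)
#' @param x metadata table; `path` file path.
#' @param path file path.
#' @return the path (write) or the validated table (read).
#' @export
write_sample_meta <- function(x, path) {
  stopifnot(all(c("sample_id", "group", "age") %in% names(x)))
  data.table::fwrite(x[, c("sample_id", "group", "age"), with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  if (!all(c("sample_id", "group", "age") %in% names(x)))
    stop("malformed metadata file: need sample_id, group, age")
  bad <- which(!x$group %in% c("case", "control"))
  if (length(bad)) stop("unknown group label at line ", bad[1] + 1L)
  x
}

#' Write / read a ground-truth effects table
#' @param x effects table from [make_true_effects()].
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_effects <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) data.table::fread(path, sep = "\t")

#' Simulate merged counts for a single region
#'
#' Monte-Carlo shortcut that draws merged (strand-combined) methylated and
#' total counts for one region directly, bypassing the strand layer: depth
#' is negative-binomial with mean `depth_mean` (per merged CpG), methylated
#' counts are beta-binomial with intra-class correlation `rho` around
#' `plogis(beta0 + D * beta_disease + age_c * beta_age)`. Used heavily in
#' calibration, power and recovery studies where only the regional model is
#' exercised.
#'
#' @param positions CpG positions (strictly increasing bp).
#' @param design data.frame with `disease` (0/1) and optional `age`
#'   (already on the scale the effects expect).
#' @param beta0,beta_disease,beta_age logit-scale effect vectors (recycled
#'   if scalar) aligned to `positions`.
#' @param depth_mean mean merged read depth per CpG.
#' @param depth_dispersion negative-binomial dispersion (0 = Poisson).
#' @param rho beta-binomial intra-class correlation.
#' @param missing_rate probability a sample x CpG record is dropped.
#' @param seed RNG seed.
#' @return list with matrices `meth`, `total` (CpG x sample; dropped
#'   records have `total = 0`).
#' @export
simulate_region_counts <- function(positions, design, beta0 = -0.5,
                                   beta_disease = 0, beta_age = 0,
                                   depth_mean = 36, depth_dispersion = 0.3,
                                   rho = 0.05, missing_rate = 0, seed = 1L) {
  n_cpg <- length(positions)
  n_s <- nrow(design)
  rec <- function(v) if (length(v) == 1L) rep(v, n_cpg) else {
    stopifnot(length(v) == n_cpg); v }
  b0 <- rec(beta0); b1 <- rec(beta_disease); b2 <- rec(beta_age)
  age <- if ("age" %in% names(design) && !is.null(design$age))
    design$age else rep(0, n_s)
  with_seed(seed, {
    meth <- matrix(0L, n_cpg, n_s)
    total <- matrix(0L, n_cpg, n_s)
    for (i in seq_len(n_s)) {
      eta <- b0 + design$disease[i] * b1 + age[i] * b2
      p <- stats::plogis(eta)
      tot <- if (depth_dispersion > 0)
        stats::rnbinom(n_cpg, mu = depth_mean, size = 1 / depth_dispersion)
      else stats::rpois(n_cpg, depth_mean)
      m <- rbetabinom(n_cpg, tot, p, rho)
      if (missing_rate > 0) {
        drop <- stats::runif(n_cpg) < missing_rate
        tot[drop] <- 0L; m[drop] <- 0L
      }
      total[, i] <- tot; meth[, i] <- m
    }
    list(meth = meth, total = total)
  })
}
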