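#' Simulate a multi-lake seasonal plankton study with known ground truth
#'
#' Generates per-lake OTU count time series mimicking a fortnightly,
#' three-season sampling campaign over several nearby shallow lakes: a
#' core community shared by all lakes plus lake-specific non-core taxa,
#' unimodal (Gaussian-bump) seasonal abundance trajectories on the log
#' scale, planted synchronous and one-step-lagged positive/negative
#' associations, desiccation events that remove samples and replace part
#' of the community on refill, and multinomial read sampling at fixed
#' depth. The returned truth object records everything that was planted,
#' so downstream inference (core partitioning, turnover, association
#' networks, keystones) can be scored against it.
#'
#' The latent log-abundance of OTU \eqn{k} at time \eqn{t} is
#' \deqn{baseline_k + amplitude_k \exp(-(t - peak_k)^2 / (2 width_k^2)) + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}. For a planted edge
#' \eqn{(a, b, sign, delay, \rho)} the partner series is built directly
#' from the driver's standardised latent series,
#' \eqn{b_t = \rho\,(\pm a_{t-delay}) + \sqrt{1-\rho^2}\,\eta_t}
#' (independent noise where the lag runs off the series), so the partner
#' has no seasonal bump of its own and recovery failures are attributable
#' to read sampling, not generator artefacts. Counts are drawn
#' multinomially per sample at `depth` reads.
#'
#' Defaults mirror a five-lake, fourteen-occasion design with spring =
#' times 1-4, summer = 5-10, autumn = 11-14, and two lakes that dry out
#' (occasions 7,8,10,11,13 and 11,13 respectively); on the first wet
#' occasion after a gap a fraction `phi` of the community mass is replaced
#' by that lake's non-core taxa.
#'
#' @param n_lakes number of lakes (default 5).
#' @param n_times number of sampling occasions (default 14; must be >= 4).
#' @param n_core number of core OTUs shared by all lakes.
#' @param n_noncore_per_lake lake-specific OTUs per lake.
#' @param depth sequencing depth per sample (>= 100 reads).
#' @param n_edges number of planted associations (drawn on disjoint core
#'   OTU pairs, mixed signs, delays in `edge_delays`).
#' @param rho coupling strength of planted edges, in (0, 1].
#' @param edge_delays candidate delays for planted edges.
#' @param planted_edges optional explicit edge list (data.frame with
#'   columns `otu_a`, `otu_b`, `sign`, `delay`, `rho`) overriding the
#'   random draw; drivers (`otu_a`) may repeat, so hubs can be planted,
#'   but no partner (`otu_b`) may drive another edge or repeat.
#' @param seasons named list of integer vectors partitioning `1:n_times`
#'   into seasons; default thirds-of-season layout for 14 occasions.
#' @param desiccation named list lake -> integer vector of dry occasions;
#'   `NULL` gives the default two drying lakes (when `n_lakes >= 5` and
#'   `n_times == 14`), `list()` disables drying.
#' @param phi post-refill replacement fraction in \[0, 1\].
#' @param noise_sd sd of the latent log-abundance noise.
#' @param baseline_sd sd of per-OTU log baselines.
#' @param amplitude_range,width_range ranges for the seasonal bump.
#' @param seed integer master seed; the same seed reproduces the study
#'   byte for byte.
#' @return list with `tables` (named list of per-lake [otutab] counts,
#'   dry occasions absent), `metadata` (one row per lake x occasion,
#'   with `sample_id`, `lake`, `time_index`, `season`, `missing` and a few
#'   synthetic environmental variables), and `truth` (class
#'   `synthetic_truth`: core ids, per-lake non-core ids, planted edges,
#'   seasonal profiles, desiccation schedule, phi, seed).
#' @examples
#' study <- generate_study(n_lakes = 2, n_times = 8, n_core = 12,
#'                         n_noncore_per_lake = 4, depth = 500,
#'                         n_edges = 2, seed = 42)
#' names(study$tables)
#' study$truth$planted_edges
#' @export
generate_study <- function(n_lakes = 5, n_times = 14, n_core = 40,
                           n_noncore_per_lake = 15, depth = 5000,
                           n_edges = 10, rho = 0.9,
                           edge_delays = c(-1L, 0L, 1L),
                           planted_edges = NULL,
                           seasons = NULL, desiccation = NULL, phi = 0.3,
                           noise_sd = 0.3, baseline_sd = 0.7,
                           amplitude_range = c(1, 2.5),
                           width_range = c(1, 3), seed = 1L) {
  if (n_times < 4) stop("n_times must be >= 4")
  if (depth < 100) stop("depth must be >= 100")
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]")
  if (is.null(planted_edges) && 2L * n_edges > n_core)
    stop("need n_core >= 2 * n_edges for disjoint planted pairs")
  if (is.null(seasons)) seasons <- default_seasons(n_times)
  validate_seasons(seasons, n_times)
  lakes <- paste0("lake", seq_len(n_lakes))
  if (is.null(desiccation)) {
    desiccation <- if (n_lakes >= 5 && n_times == 14)
      list(lake4 = c(11L, 13L), lake5 = c(7L, 8L, 10L, 11L, 13L))
    else list()
  }
  if (!all(names(desiccation) %in% lakes))
    stop("desiccation names unknown lakes")

  core_ids <- sprintf("core_%03d", seq_len(n_core))
  noncore_map <- lapply(seq_len(n_lakes), function(l)
    sprintf("%s_nc_%03d", lakes[l], seq_len(n_noncore_per_lake)))
  names(noncore_map) <- lakes

  withr::with_seed(as.integer(seed), {
    # seasonal profiles for all OTUs (partner OTUs of planted edges will
    # override theirs with the coupling construction)
    all_ids <- c(core_ids, unlist(noncore_map, use.names = FALSE))
    profiles <- data.frame(
      otu_id = all_ids,
      baseline = stats::rnorm(length(all_ids), 0, baseline_sd),
      peak = stats::runif(length(all_ids), 1, n_times),
      width = stats::runif(length(all_ids), width_range[1], width_range[2]),
      amplitude = stats::runif(length(all_ids), amplitude_range[1],
                               amplitude_range[2]),
      stringsAsFactors = FALSE
    )

    planted <- NULL
    if (!is.null(planted_edges)) {
      planted <- as.data.frame(planted_edges, stringsAsFactors = FALSE)
      need <- c("otu_a", "otu_b", "sign", "delay", "rho")
      if (!all(need %in% names(planted)))
        stop("planted_edges needs columns ", paste(need, collapse = ", "))
      planted$delay <- as.integer(planted$delay)
      if (!all(planted$delay %in% as.integer(edge_delays)))
        stop("planted delay outside the configured delay limit")
      if (!all(c(planted$otu_a, planted$otu_b) %in% core_ids))
        stop("planted edge members must be core OTU ids")
      if (anyDuplicated(planted$otu_b) ||
          any(planted$otu_b %in% planted$otu_a))
        stop("planted partners (otu_b) must be unique and must not drive other edges")
    } else if (n_edges > 0) {
      members <- sample(core_ids, 2L * n_edges)
      planted <- data.frame(
        otu_a = members[seq_len(n_edges)],
        otu_b = members[n_edges + seq_len(n_edges)],
        sign = sample(c("+", "-"), n_edges, replace = TRUE),
        delay = as.integer(sample(edge_delays, n_edges, replace = TRUE)),
        rho = rep(rho, n_edges),
        stringsAsFactors = FALSE
      )
    }

    tables <- vector("list", n_lakes)
    names(tables) <- lakes
    meta <- NULL
    for (l in lakes) {
      ids_l <- c(core_ids, noncore_map[[l]])
      prof_l <- profiles[match(ids_l, profiles$otu_id), ]
      tt <- seq_len(n_times)
      latent <- sapply(seq_along(ids_l), function(k) {
        prof_l$baseline[k] +
          prof_l$amplitude[k] *
            exp(-(tt - prof_l$peak[k])^2 / (2 * prof_l$width[k]^2)) +
          stats::rnorm(n_times, 0, noise_sd)
      })
      colnames(latent) <- ids_l
      if (!is.null(planted)) {
        for (e in seq_len(nrow(planted))) {
          a <- planted$otu_a[e]; b <- planted$otu_b[e]
          s <- if (planted$sign[e] == "+") 1 else -1
          d <- planted$delay[e]; r <- planted$rho[e]
          az <- as.numeric(scale(latent[, a]))
          # both members of a planted pair carry unit latent dynamic
          # range, so realised pair correlation reflects rho plus read
          # sampling noise, not an arbitrary driver amplitude
          latent[, a] <- profiles$baseline[match(a, profiles$otu_id)] + az
          src <- tt - d
          shifted <- ifelse(src >= 1 & src <= n_times,
                            az[pmin(pmax(src, 1L), n_times)],
                            stats::rnorm(n_times))
          bb <- r * s * shifted + sqrt(1 - r^2) * stats::rnorm(n_times)
          latent[, b] <- profiles$baseline[match(b, profiles$otu_id)] + bb
        }
      }

      dry <- desiccation[[l]]
      if (is.null(dry)) dry <- integer(0)
      present <- setdiff(tt, dry)
      probs <- exp(latent)
      # post-refill replacement: shift phi of the mass onto non-core taxa
      if (length(dry) && phi > 0) {
        # first present occasion after each maximal dry run
        runs <- split(dry, cumsum(c(1, diff(dry) != 1)))
        refill <- unique(unlist(lapply(runs, function(rn) {
          after <- present[present > max(rn)]
          if (length(after)) min(after) else integer(0)
        })))
        nc <- noncore_map[[l]]
        for (t in refill) {
          p <- probs[t, ] / sum(probs[t, ])
          q <- numeric(length(p)); names(q) <- colnames(probs)
          w <- probs[t, nc] / sum(probs[t, nc])
          q[nc] <- w
          probs[t, ] <- (1 - phi) * p + phi * q
        }
      }

      counts <- t(sapply(present, function(t)
        as.numeric(stats::rmultinom(1, depth, probs[t, ]))))
      dimnames(counts) <- list(sprintf("%s_t%02d", l, present), ids_l)
      tables[[l]] <- otutab(counts)

      season_of <- season_labels(seasons, n_times)
      env_temp <- 12 + 10 * sin(pi * (tt - 1) / (n_times - 1)) +
        stats::rnorm(n_times, 0, 1)
      env_depth <- pmax(1.5, 40 - 2.2 * tt + stats::rnorm(n_times, 0, 3))
      env_ec <- pmax(1, 8 + 0.4 * tt + stats::rnorm(n_times, 0, 1))
      meta_l <- data.frame(
        sample_id = sprintf("%s_t%02d", l, tt),
        lake = l,
        time_index = tt,
        season = season_of,
        missing = tt %in% dry,
        temperature = round(env_temp, 2),
        water_depth = round(env_depth, 1),
        ec = round(env_ec, 2),
        stringsAsFactors = FALSE
      )
      meta_l[meta_l$missing, c("temperature", "water_depth", "ec")] <- NA
      meta <- rbind(meta, meta_l)
    }
  })

  truth <- structure(list(
    core_otus = core_ids,
    noncore_map = noncore_map,
    planted_edges = planted,
    seasonal_profiles = profiles,
    desiccation = desiccation,
    phi = phi,
    seed = as.integer(seed)
  ), class = "synthetic_truth")

  list(tables = tables, metadata = meta, truth = truth)
}

default_seasons <- function(n_times) {
  if (n_times == 14)
    return(list(spring = 1:4, summer = 5:10, autumn = 11:14))
  cut <- round(stats::quantile(seq_len(n_times), c(0.3, 0.7)))
  list(spring = seq_len(cut[1]),
       summer = seq(cut[1] + 1, cut[2]),
       autumn = seq(cut[2] + 1, n_times))
}

validate_seasons <- function(seasons, n_times) {
  idx <- sort(unlist(seasons, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(n_times)))
    stop("seasons must partition 1..n_times disjointly")
  invisible(TRUE)
}

season_labels <- function(seasons, n_times) {
  out <- character(n_times)
  for (s in names(seasons)) out[seasons[[s]]] <- s
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d core OTUs, %d lakes, %d planted edges, phi = %g\n",
              length(x$core_otus), length(x$noncore_map),
              if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges),
              x$phi))
  invisible(x)
}

#' Canonical catalogue of planted associations
#'
#' Reorders every planted edge so that `otu_a < otu_b` lexicographically,
#' flipping the delay sign accordingly (a lag of the second member on the
#' first becomes a lead after the swap). Duplicate pairs collapse to a
#' single record keeping the strongest coupling. Use it to compare
#' inferred association tables with the ground truth.
#'
#' @param truth a `synthetic_truth` object from [generate_study()].
#' @return data.frame with columns `otu_a`, `otu_b`, `sign`, `delay`,
#'   `rho`, canonically ordered and deduplicated.
#' @export
planted_edge_catalogue <- function(truth) {
  pe <- truth$planted_edges
  if (is.null(pe) || nrow(pe) == 0)
    return(data.frame(otu_a = character(), otu_b = character(),
                      sign = character(), delay = integer(),
                      rho = numeric(), stringsAsFactors = FALSE))
  swap <- pe$otu_a > pe$otu_b
  out <- pe
  out$otu_a <- ifelse(swap, pe$otu_b, pe$otu_a)
  out$otu_b <- ifelse(swap, pe$otu_a, pe$otu_b)
  out$delay <- ifelse(swap, -pe$delay, pe$delay)
  key <- paste(out$otu_a, out$otu_b)
  out <- out[order(key, -out$rho), ]
  out <- out[!duplicated(paste(out$otu_a, out$otu_b)), ]
  rownames(out) <- NULL
  out
}
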