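#' Simulate a constant-rate birth-death phylogeny with n surviving tips
#'
#' Wraps [ape::rphylo()] (conditioned on the number of surviving tips) with
#' seed handling and tip relabelling to synthetic binomials
#' (`Genus01_sp001`, ...), so fixtures look like the plant name data the
#' pipeline ingests. The result is ultrametric.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates (`birth > death >= 0`).
#' @param seed Integer seed.
#' @param n_genera Number of synthetic genera to spread tips across.
#' @return Ultrametric `phylo` with unique tip labels.
#' @export
simulate_bd_tree <- function(n_tips, birth = 1, death = 0, seed = 1L,
                             n_genera = max(2L, n_tips %/% 5L)) {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  genus_id <- sort(rep_len(seq_len(n_genera), n_tips))
  labels <- sprintf("Genus%02d_sp%03d", genus_id, seq_len(n_tips))
  tree$tip.label[seq_len(n_tips)] <- labels
  tree
}

#' Configuration for synthetic community assembly
#'
#' Defaults emulate the shape of the compiled global dataset this pipeline
#' targets: several hundred communities nested in tens of studies, latitudes
#' spanning roughly 55 degrees S to 61 degrees N, six biogeographic realms,
#' three vegetation classes, and phylogenetic clustering whose strength
#' varies with latitude through the kernel scale `tau`.
#'
#' `tau` is expressed as a multiple of the pool's median pairwise distance
#' and is log-linearly interpolated in `|latitude| / max |latitude|` between
#' `tau_at_equator` and `tau_at_pole`; `tau_at_equator < tau_at_pole` makes
#' communities near the equator more clustered (the woody-type pattern),
#' the reverse makes high latitudes clustered, and `clustering = "none"`
#' gives uniform assembly.
#'
#' @param n_studies,communities_per_study Sampling design.
#' @param richness_range Integer range communities' richness is drawn from.
#' @param lat_range Latitude range studies are placed in (decimal degrees).
#' @param tau_at_equator,tau_at_pole Kernel scale at the extremes (multiples
#'   of the median pairwise distance).
#' @param clustering `"equator"` (stronger near 0 degrees), `"poles"`
#'   (stronger at high latitude), or `"none"` (uniform draws).
#' @param growth_form Stratum label attached to every record.
#' @param log10_size_range Range of log10 sampling-unit size (m^2).
#' @param climate Attach synthetic `temperature`/`precipitation` covariates
#'   (monotone in absolute latitude, so the Pearson screen has signal).
#' @param seed Master seed.
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(n_studies = 40L, communities_per_study = 10L,
                            richness_range = c(5L, 25L),
                            lat_range = c(-55, 61),
                            tau_at_equator = 0.1, tau_at_pole = 2,
                            clustering = c("equator", "poles", "none"),
                            growth_form = "woody",
                            log10_size_range = c(0, 6),
                            climate = TRUE,
                            seed = 1L) {
  clustering <- match.arg(clustering)
  if (clustering == "poles") {
    swapped <- c(tau_at_pole, tau_at_equator)
    tau_at_equator <- swapped[1]; tau_at_pole <- swapped[2]
  }
  stopifnot(tau_at_equator > 0, tau_at_pole > 0,
            richness_range[1] >= 3L, lat_range[1] < lat_range[2])
  cfg <- mget(c("n_studies", "communities_per_study", "richness_range",
                "lat_range", "tau_at_equator", "tau_at_pole", "clustering",
                "growth_form", "log10_size_range", "climate", "seed"))
  structure(cfg, class = "assembly_config")
}

#' Assemble synthetic communities on a phylogeny
#'
#' Each community starts from a uniformly drawn focal tip; the remaining
#' members are drawn without replacement with probability proportional to
#' `exp(-d(focal, tip) / tau(latitude))`, so a small `tau` confines the
#' community to the focal tip's neighbourhood of the tree (phylogenetic
#' clustering) and a large `tau` approaches uniform assembly. Studies get a
#' latitude, longitude and realm; communities inherit the study location
#' with a small jitter and get a vegetation class and sampling-unit size.
#'
#' @param tree Species-pool phylogeny (tips = pool).
#' @param cfg An [assembly_config()].
#' @return A `community_table` with covariates (and a `focal` column in the
#'   members table for diagnostics).
#' @export
assemble_communities <- function(tree, cfg) {
  stopifnot(inherits(cfg, "assembly_config"))
  pool <- tree$tip.label
  if (max(cfg$richness_range) > length(pool))
    stop("richness range exceeds pool size", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)

  dm <- pairwise_distances(tree)
  med_d <- stats::median(dm[upper.tri(dm)])
  max_abs_lat <- max(abs(cfg$lat_range))
  tau_of <- function(lat) {
    if (cfg$clustering == "none") return(Inf)
    u <- abs(lat) / max_abs_lat
    med_d * exp((1 - u) * log(cfg$tau_at_equator) + u * log(cfg$tau_at_pole))
  }

  members <- list(); covars <- list()
  for (s in seq_len(cfg$n_studies)) {
    study_id <- sprintf("study%03d", s)
    s_lat <- stats::runif(1, cfg$lat_range[1], cfg$lat_range[2])
    s_lon <- stats::runif(1, -180, 180)
    realm <- sample(REALMS, 1)
    for (c_i in seq_len(cfg$communities_per_study)) {
      community_id <- sprintf("comm%02d", c_i)
      lat <- max(cfg$lat_range[1], min(cfg$lat_range[2], s_lat + stats::rnorm(1, 0, 0.5)))
      lon <- s_lon + stats::rnorm(1, 0, 0.5)
      rich_opts <- seq(cfg$richness_range[1], cfg$richness_range[2])
      rich <- rich_opts[sample.int(length(rich_opts), 1)]
      tau <- tau_of(lat)
      focal <- sample(length(pool), 1)
      others <- setdiff(seq_along(pool), focal)
      w <- if (is.finite(tau)) exp(-dm[focal, others] / tau) else rep(1, length(others))
      w <- pmax(w, 1e-12)
      picks <- c(focal, sample(others, rich - 1L, prob = w))
      members[[length(members) + 1L]] <- data.frame(
        study_id = study_id, community_id = community_id,
        species = pool[picks], growth_form = cfg$growth_form,
        focal = pool[focal], stringsAsFactors = FALSE
      )
      veg <- sample(VEGETATION_CLASSES, 1, prob = c(0.4, 0.4, 0.2))
      cov_row <- data.frame(
        study_id = study_id, community_id = community_id,
        latitude = lat, longitude = lon,
        size = 10^stats::runif(1, cfg$log10_size_range[1], cfg$log10_size_range[2]),
        realm = realm, vegetation = veg, stringsAsFactors = FALSE
      )
      if (cfg$climate) {
        cov_row$temperature <- 28 - 0.45 * abs(lat) + stats::rnorm(1, 0, 2)
        cov_row$precipitation <- pmax(50, 2200 * exp(-abs(lat) / 30) +
                                        stats::rnorm(1, 0, 150))
      }
      covars[[length(covars) + 1L]] <- cov_row
    }
  }
  read_communities(do.call(rbind, members), do.call(rbind, covars))
}

#' Simulate a mixed-model response with known ground truth
#'
#' `y = X beta + b_study + e` with `b_study ~ N(0, sigma_study^2)` iid and
#' residuals independent, or exponentially spatially correlated within
#' study when `rho` is supplied.
#'
#' @param X Design matrix.
#' @param groups Grouping factor (length `nrow(X)`).
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param sigma_study,sigma_resid Standard deviations (>= 0).
#' @param rho Optional spatial range (with `coords`).
#' @param coords Optional coordinates (see [lmm_loglik()]).
#' @param coord_type `"geo"` or `"euclidean"`.
#' @param seed Integer seed.
#' @return Numeric response vector.
#' @export
simulate_response <- function(X, groups, beta, sigma_study = 1,
                              sigma_resid = 1, rho = NULL, coords = NULL,
                              coord_type = c("geo", "euclidean"), seed = 1L) {
  coord_type <- match.arg(coord_type)
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop("beta length != ncol(X)", call. = FALSE)
  if (length(groups) != nrow(X)) stop("groups length != nrow(X)", call. = FALSE)
  stopifnot(sigma_study >= 0, sigma_resid >= 0)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  groups <- as.factor(groups)
  y <- drop(X %*% beta)
  b <- stats::rnorm(nlevels(groups), 0, sigma_study)
  y <- y + b[as.integer(groups)]
  if (is.null(rho)) {
    y + stats::rnorm(nrow(X), 0, sigma_resid)
  } else {
    for (g in levels(groups)) {
      i <- which(groups == g)
      R <- exp(-group_dist(coords[i, , drop = FALSE], coord_type) / rho)
      e <- drop(crossprod(chol(sigma_resid^2 * R), stats::rnorm(length(i))))
      y[i] <- y[i] + e
    }
    y
  }
}

#' Ready-made synthetic study fixtures
#'
#' `"tiny"` builds a 16-tip tree and 12 communities in 4 studies (small
#' enough for exhaustive nulls); `"paper-like"` builds a 500-tip tree and
#' 400 communities in 40 studies with latitude-dependent clustering, the
#' scale at which the full analysis is exercised.
#'
#' @param profile `"tiny"` or `"paper-like"`.
#' @param seed Master seed.
#' @param clustering Passed to [assembly_config()].
#' @return List with `tree`, `communities` (a `community_table`), and `cfg`.
#' @export
generate_study_fixture <- function(profile = c("tiny", "paper-like"),
                                   seed = 1L,
                                   clustering = "equator") {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    tree <- simulate_bd_tree(16L, seed = seed)
    cfg <- assembly_config(
      n_studies = 4L, communities_per_study = 3L, richness_range = c(3L, 6L),
      clustering = clustering, seed = seed + 1L
    )
  } else {
    tree <- simulate_bd_tree(500L, seed = seed)
    cfg <- assembly_config(
      n_studies = 40L, communities_per_study = 10L,
      richness_range = c(5L, 25L), clustering = clustering, seed = seed + 1L
    )
  }
  list(tree = tree, communities = assemble_communities(tree, cfg), cfg = cfg)
}
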