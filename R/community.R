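#' Read community membership and covariate tables
#'
#' Membership is long format (`study_id`, `community_id`, `species`,
#' `growth_form`); covariates are keyed by (`study_id`, `community_id`) and
#' carry `latitude`, `longitude`, `size` (sampling-unit area), `realm`,
#' `vegetation`, and optionally `temperature` and `precipitation`.
#' Duplicate (community, species) rows are collapsed with a warning;
#' communities without a covariate row are flagged and excluded from
#' modelling downstream.
#'
#' @param membership Data frame or CSV path (long format, see above).
#' @param covariates Data frame or CSV path keyed by study and community id.
#' @return A `community_table`: list with `members`, `covariates`,
#'   `exclusions` (provenance log, initially empty or holding covariate-less
#'   communities).
#' @export
read_communities <- function(membership, covariates) {
  if (is.character(membership)) membership <- utils::read.csv(membership, stringsAsFactors = FALSE)
  if (is.character(covariates)) covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  need_m <- c("study_id", "community_id", "species", "growth_form")
  if (!all(need_m %in% names(membership)))
    stop("membership table missing columns: ",
         paste(setdiff(need_m, names(membership)), collapse = ", "), call. = FALSE)
  need_c <- c("study_id", "community_id", "latitude", "longitude", "size",
              "realm", "vegetation")
  if (!all(need_c %in% names(covariates)))
    stop("covariate table missing columns: ",
         paste(setdiff(need_c, names(covariates)), collapse = ", "), call. = FALSE)

  key <- paste(membership$study_id, membership$community_id, membership$species, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (community, species) rows collapsed",
            call. = FALSE)
    membership <- membership[!duplicated(key), , drop = FALSE]
  }
  ckey_m <- unique(paste(membership$study_id, membership$community_id, sep = "\r"))
  ckey_c <- paste(covariates$study_id, covariates$community_id, sep = "\r")
  if (anyDuplicated(ckey_c))
    stop("duplicate (study_id, community_id) rows in covariate table", call. = FALSE)

  missing_cov <- setdiff(ckey_m, ckey_c)
  exclusions <- data.frame(
    study_id = character(0), community_id = character(0), reason = character(0),
    stringsAsFactors = FALSE
  )
  if (length(missing_cov)) {
    parts <- strsplit(missing_cov, "\r", fixed = TRUE)
    exclusions <- data.frame(
      study_id = vapply(parts, `[[`, character(1), 1L),
      community_id = vapply(parts, `[[`, character(1), 2L),
      reason = "missing covariates",
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(members = membership, covariates = covariates, exclusions = exclusions),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  n_comm <- length(unique(paste(x$members$study_id, x$members$community_id)))
  cat("community_table:", n_comm, "communities in",
      length(unique(x$members$study_id)), "studies;",
      length(unique(x$members$species)), "species;",
      nrow(x$exclusions), "logged exclusions\n")
  invisible(x)
}

#' Default raw-label to vegetation-class mapping
#'
#' Forest communities are closed; grassland, meadow, salt marsh, outcrop and
#' dune communities are open; savanna and scrubland communities are
#' semi-open. Extend by rbinding rows.
#'
#' @return Data frame with columns `label`, `class`.
#' @export
default_vegetation_map <- function() {
  data.frame(
    label = c("forest",
              "grassland", "meadow", "salt marsh", "outcrop", "dune",
              "savanna", "scrubland"),
    class = c("closed",
              "open", "open", "open", "open", "open",
              "semi-open", "semi-open"),
    stringsAsFactors = FALSE
  )
}

#' Reclassify raw vegetation labels into closed / open / semi-open
#'
#' @param labels Character vector of raw vegetation labels.
#' @param mapping Data frame `label`, `class` (default
#'   [default_vegetation_map()]).
#' @return Character vector of vegetation classes.
#' @export
classify_vegetation <- function(labels, mapping = default_vegetation_map()) {
  labels_norm <- tolower(trimws(labels))
  idx <- match(labels_norm, tolower(mapping$label))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown vegetation label(s): ", paste(bad, collapse = ", "),
         "; admissible labels: ", paste(mapping$label, collapse = ", "),
         call. = FALSE)
  }
  mapping$class[idx]
}

#' Admissible biogeographic realms
#' @export
REALMS <- c("Afrotropical", "Australasian", "Indo-Malayan",
            "Nearctic", "Neotropical", "Palearctic")

#' Admissible vegetation classes
#' @export
VEGETATION_CLASSES <- c("closed", "open", "semi-open")

#' Filter a community table to the analysis-ready set
#'
#' Applies, in order: optional gymnosperm removal (for the sensitivity
#' analysis), removal of communities with fewer than `min_richness` species,
#' and removal of mixed growth-form communities. Every exclusion is appended
#' to the provenance log with its reason. Filtering is idempotent.
#'
#' @param ct A `community_table`.
#' @param min_richness Minimum species richness retained (default 3).
#' @param exclude_gymnosperms Remove gymnosperm species before the richness
#'   rule is (re-)applied.
#' @param taxa Data frame with columns `species`, `gymnosperm` (logical);
#'   required when `exclude_gymnosperms = TRUE`.
#' @return The filtered `community_table`.
#' @export
apply_filters <- function(ct, min_richness = 3L, exclude_gymnosperms = FALSE,
                          taxa = NULL) {
  stopifnot(inherits(ct, "community_table"))
  m <- ct$members
  excl <- ct$exclusions

  if (exclude_gymnosperms) {
    if (is.null(taxa) || !all(c("species", "gymnosperm") %in% names(taxa)))
      stop("gymnosperm exclusion requires a 'taxa' table with columns ",
           "'species' and 'gymnosperm'", call. = FALSE)
    gym <- taxa$species[isTRUE_vec(taxa$gymnosperm)]
    m <- m[!(m$species %in% gym), , drop = FALSE]
  }

  ckey <- paste(m$study_id, m$community_id, sep = "\r")
  # drop communities already excluded (e.g. missing covariates)
  if (nrow(excl)) {
    bad <- paste(excl$study_id, excl$community_id, sep = "\r")
    keep <- !(ckey %in% bad)
    m <- m[keep, , drop = FALSE]
    ckey <- ckey[keep]
  }

  rich <- table(ckey)
  low <- names(rich)[rich < min_richness]
  mixed <- names(which(tapply(m$growth_form, ckey, function(g) length(unique(g)) > 1)))

  drop_log <- function(keys, reason) {
    if (!length(keys)) return(NULL)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(
      study_id = vapply(parts, `[[`, character(1), 1L),
      community_id = vapply(parts, `[[`, character(1), 2L),
      reason = reason, stringsAsFactors = FALSE
    )
  }
  excl <- rbind(
    excl,
    drop_log(low, sprintf("richness < %d", min_richness)),
    drop_log(setdiff(mixed, low), "mixed growth forms")
  )
  m <- m[!(ckey %in% c(low, mixed)), , drop = FALSE]

  structure(list(members = m, covariates = ct$covariates, exclusions = excl),
            class = "community_table")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Pearson screen of latitude against climate covariates
#'
#' Reports the correlation between (absolute) latitude and each available
#' climate covariate, used to justify dropping collinear climate variables
#' from the model set.
#'
#' @param ct A `community_table` whose covariates include `temperature`
#'   and/or `precipitation`.
#' @param use_abs_latitude Correlate against `abs(latitude)` (default TRUE;
#'   climate varies with distance from the equator, not hemisphere).
#' @return Data frame with columns `variable`, `r`, `n`, `defined`.
#' @export
latitude_climate_screen <- function(ct, use_abs_latitude = TRUE) {
  cov <- ct$covariates
  lat <- if (use_abs_latitude) abs(cov$latitude) else cov$latitude
  vars <- intersect(c("temperature", "precipitation"), names(cov))
  if (!length(vars)) stop("no climate covariates present", call. = FALSE)
  out <- lapply(vars, function(v) {
    ok <- stats::complete.cases(lat, cov[[v]])
    n <- sum(ok)
    if (n < 3L) stop("need at least 3 communities with '", v, "'", call. = FALSE)
    if (stats::sd(lat[ok]) == 0 || stats::sd(cov[[v]][ok]) == 0)
      return(data.frame(variable = v, r = NA_real_, n = n, defined = FALSE))
    data.frame(variable = v, r = stats::cor(lat[ok], cov[[v]][ok]), n = n,
               defined = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Species pool of a community table
#'
#' Union of species across the table's communities: the reference list from
#' which the stratum tree is pruned and nulls are drawn.
#'
#' @param ct A `community_table`.
#' @return Character vector of species names.
#' @export
species_pool <- function(ct) sort(unique(ct$members$species))
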