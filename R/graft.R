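#' Canonicalize taxon names against a local synonym table
#'
#' Names are whitespace-normalized (capitalized genus, lower-case epithet),
#' then resolved through the synonym table to a fixed point, so the operation
#' is idempotent. Single-word names become genus-level records
#' (`"Genus sp."`). This replaces remote taxonomic-service lookups with a
#' fully local, reproducible step.
#'
#' @param names Character vector of input names (no empty strings).
#' @param synonyms Optional data frame with columns `variant`, `canonical`
#'   (or a 2-column data frame in that order), or a path to such a CSV.
#' @return Data frame with columns `input`, `canonical`, `genus`,
#'   `genus_level`.
#' @export
canonicalize_names <- function(names, synonyms = NULL) {
  names <- as.character(names)
  if (any(is.na(names)) || any(!nzchar(trimws(names))))
    stop("empty taxon name", call. = FALSE)
  map <- load_synonym_table(synonyms)

  canon1 <- vapply(names, normalize_binomial, character(1), USE.NAMES = FALSE)
  canon <- canon1
  for (i in seq_along(canon)) {
    seen <- canon[i]
    # resolve chains variant -> canonical -> ... to a fixed point
    repeat {
      nxt <- map[[canon[i]]]
      if (is.null(nxt)) break
      nxt <- normalize_binomial(nxt)
      if (nxt == canon[i] || nxt %in% seen) break
      seen <- c(seen, nxt)
      canon[i] <- nxt
    }
  }
  genus <- vapply(strsplit(canon, " ", fixed = TRUE), `[[`, character(1), 1L)
  data.frame(
    input = names,
    canonical = canon,
    genus = genus,
    genus_level = grepl(" sp\\.$", canon),
    stringsAsFactors = FALSE
  )
}

load_synonym_table <- function(synonyms) {
  if (is.null(synonyms)) return(list())
  if (is.character(synonyms) && length(synonyms) == 1L) {
    synonyms <- utils::read.csv(synonyms, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(synonyms), ncol(synonyms) >= 2L)
  cols <- if (all(c("variant", "canonical") %in% names(synonyms)))
    c("variant", "canonical") else names(synonyms)[1:2]
  key <- vapply(synonyms[[cols[1]]], normalize_binomial, character(1), USE.NAMES = FALSE)
  stats::setNames(as.list(as.character(synonyms[[cols[2]]])), key)
}

normalize_binomial <- function(x) {
  parts <- strsplit(trimws(gsub("[\\s_]+", " ", x, perl = TRUE)), " ")[[1]]
  if (length(parts) == 0L) stop("empty taxon name", call. = FALSE)
  genus <- paste0(toupper(substring(parts[1], 1, 1)), tolower(substring(parts[1], 2)))
  if (length(parts) == 1L) return(paste(genus, "sp."))
  paste(genus, paste(tolower(parts[-1]), collapse = " "))
}

#' Build a tip-to-genus/family index from tip labels
#'
#' Tip labels of the reference tree are assumed `Genus_species` or
#' `Genus species`; the genus is the leading word. Families are joined from
#' an optional genus-to-family table.
#'
#' @param tree A `phylo` object.
#' @param family_map Optional data frame `genus`, `family` (or CSV path).
#' @return Data frame with columns `tip`, `genus`, `family` (`NA` when
#'   unknown).
#' @export
build_taxon_index <- function(tree, family_map = NULL) {
  tips <- tree$tip.label
  genus <- sub("[ _].*$", "", tips)
  fam <- rep(NA_character_, length(tips))
  if (!is.null(family_map)) {
    if (is.character(family_map) && length(family_map) == 1L)
      family_map <- utils::read.csv(family_map, stringsAsFactors = FALSE)
    fam <- family_map$family[match(genus, family_map$genus)]
  }
  data.frame(tip = tips, genus = genus, family = fam, stringsAsFactors = FALSE)
}

#' Graft missing taxa onto a dated reference phylogeny
#'
#' Emulates the "add within known branch lengths" placement strategy used to
#' bind community species onto a dated megaphylogeny. For each taxon absent
#' from the tree:
#' \itemize{
#'   \item if congeners are present, the new tip is attached at the genus
#'     crown node (the most recent common ancestor of the congeners) with a
#'     pendant branch equal to that node's age, creating a polytomy when
#'     several taxa attach at the same node;
#'   \item if the genus has exactly one sampled species, its pendant edge is
#'     split at `split_fraction` of its depth to create a genus crown, and
#'     the new tip attaches there;
#'   \item if the genus is absent but the family is represented, the same
#'     rules apply at the family crown;
#'   \item otherwise the taxon is reported unplaceable (no error).
#' }
#' Genus-level records (`"Genus sp."`) are placed by the genus rule. The
#' input tree must be ultrametric; the output is ultrametric and distances
#' among pre-existing tips are unchanged.
#'
#' @param tree Ultrametric `phylo`.
#' @param taxa Character vector of canonical names, or the data frame
#'   returned by [canonicalize_names()], optionally with a `family` column
#'   used for family-crown placement when the genus is absent from the tree.
#' @param taxon_index Data frame `tip`, `genus`, `family` mapping the tree's
#'   tips to higher taxa (see [build_taxon_index()]). Defaults to an index
#'   derived from tip labels (families unknown).
#' @param split_fraction Where to cut a lone congener's pendant edge when a
#'   genus crown has to be created (fraction of pendant depth, default 0.5).
#' @param rel_tol Ultrametricity tolerance for the input check.
#' @return List with `tree` (the augmented `phylo`) and `report`, a data
#'   frame with one row per input taxon: `taxon`, `outcome` (one of
#'   `already_present`, `grafted_at_genus`, `grafted_at_family`,
#'   `unplaceable`), `pendant_length`.
#' @export
graft_taxa <- function(tree, taxa, taxon_index = build_taxon_index(tree),
                       split_fraction = 0.5, rel_tol = 1e-6) {
  taxon_fam <- NULL
  if (is.data.frame(taxa)) {
    if (!is.null(taxa$family))
      taxon_fam <- stats::setNames(as.character(taxa$family), taxa$canonical)
    taxa <- taxa$canonical
  }
  taxa <- as.character(taxa)
  um <- is_ultrametric(tree, rel_tol)
  if (!um$ultrametric)
    stop("input tree is not ultrametric (relative deviation ",
         format(um$max_deviation), ")", call. = FALSE)
  stopifnot(all(c("tip", "genus") %in% names(taxon_index)))
  if (is.null(taxon_index$family)) taxon_index$family <- NA_character_

  tip_genus <- stats::setNames(taxon_index$genus, taxon_index$tip)
  tip_family <- stats::setNames(taxon_index$family, taxon_index$tip)
  genus_family <- tapply(taxon_index$family, taxon_index$genus, function(f) {
    f <- f[!is.na(f)]
    if (length(f)) f[1] else NA_character_
  })

  report <- data.frame(
    taxon = taxa,
    outcome = NA_character_,
    pendant_length = NA_real_,
    stringsAsFactors = FALSE
  )

  for (i in seq_along(taxa)) {
    name <- taxa[i]
    label <- gsub(" ", "_", name)
    genus <- sub("[ _].*$", "", name)
    present <- label %in% tree$tip.label || name %in% tree$tip.label
    if (present) {
      report$outcome[i] <- "already_present"
      next
    }
    genus_tips <- names(tip_genus)[tip_genus == genus & names(tip_genus) %in% tree$tip.label]
    if (length(genus_tips) >= 1L) {
      res <- attach_at_crown(tree, genus_tips, label, split_fraction)
      tree <- res$tree
      report$outcome[i] <- "grafted_at_genus"
      report$pendant_length[i] <- res$pendant
      tip_genus[label] <- genus
      tip_family[label] <- genus_to_family(genus_family, genus)
      next
    }
    fam <- genus_to_family(genus_family, genus)
    if (is.na(fam) && !is.null(taxon_fam) && name %in% names(taxon_fam))
      fam <- taxon_fam[[name]]
    if (!is.na(fam)) {
      fam_tips <- names(tip_family)[!is.na(tip_family) & tip_family == fam &
                                      names(tip_family) %in% tree$tip.label]
    } else fam_tips <- character(0)
    if (length(fam_tips) >= 1L) {
      res <- attach_at_crown(tree, fam_tips, label, split_fraction)
      tree <- res$tree
      report$outcome[i] <- "grafted_at_family"
      report$pendant_length[i] <- res$pendant
      tip_genus[label] <- genus
      tip_family[label] <- fam
    } else {
      report$outcome[i] <- "unplaceable"
    }
  }
  list(tree = tree, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genus_to_family <- function(genus_family, genus) {
  if (genus %in% names(genus_family)) genus_family[[genus]] else NA_character_
}

# Attach `label` at the crown of the clade spanned by `group_tips`. With two
# or more tips the crown is their MRCA; with a single tip its pendant edge is
# split at `split_fraction` of its depth to create the crown.
attach_at_crown <- function(tree, group_tips, label, split_fraction) {
  ages <- node_ages(tree)
  if (length(group_tips) >= 2L) {
    node <- ape::getMRCA(tree, group_tips)
    pendant <- ages[node]
    tree <- bind_tip_at(tree, label, where = node, pendant = pendant, position = 0)
  } else {
    tip_idx <- match(group_tips, tree$tip.label)
    edge_len <- tree$edge.length[tree$edge[, 2] == tip_idx]
    h <- split_fraction * edge_len
    pendant <- h
    tree <- bind_tip_at(tree, label, where = tip_idx, pendant = h, position = h)
  }
  list(tree = tree, pendant = pendant)
}

# Edge surgery: add a tip as a new child of node `where` (position = 0), or
# split the edge above `where` at height `position` and attach there.
# Kept minimal and index-safe by rebuilding through ape's bind.tree.
bind_tip_at <- function(tree, label, where, pendant, position = 0) {
  if (label %in% tree$tip.label)
    stop("tip already present: ", label, call. = FALSE)
  newtip <- list(
    edge = matrix(c(2L, 1L), 1, 2),
    tip.label = label,
    edge.length = pendant,
    Nnode = 1L
  )
  class(newtip) <- "phylo"
  out <- ape::bind.tree(tree, newtip, where = where, position = position)
  ape::reorder.phylo(out, "cladewise")
}

#' Interpolate missing node ages (BLADJ-style even spacing)
#'
#' Given fixed ages for a subset of nodes (the root must be fixed; tips
#' default to age 0), every undated node is aged by linear interpolation
#' between its nearest dated ancestor and its nearest dated descendant,
#' spacing the intervening nodes evenly along the path. Branch lengths are
#' recomputed from the resulting ages; fixed ages are untouched.
#'
#' @param tree A `phylo` object (topology used; branch lengths replaced).
#' @param ages Named numeric vector of fixed ages. Names are tip labels,
#'   internal node labels, or ape node numbers as strings. Must include the
#'   root.
#' @return The tree with branch lengths implied by the interpolated ages.
#' @export
interpolate_node_ages <- function(tree, ages) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  fixed <- rep(NA_real_, n_node)
  fixed[seq_len(n_tip)] <- 0  # tips default to the present
  ids <- resolve_node_ids(tree, names(ages))
  fixed[ids] <- as.numeric(ages)
  if (is.na(fixed[root]))
    stop("root age must be fixed", call. = FALSE)

  parent <- rep(NA_integer_, n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  is_fixed <- !is.na(fixed)
  # consistency: on every rootward path, fixed ages must not increase
  for (v in which(is_fixed)) {
    u <- parent[v]
    while (!is.na(u)) {
      if (is_fixed[u] && fixed[u] < fixed[v] - 1e-12)
        stop("inconsistent fixed ages: ancestor node ", u, " (", fixed[u],
             ") younger than descendant node ", v, " (", fixed[v], ")",
             call. = FALSE)
      u <- parent[u]
    }
  }

  age <- fixed
  for (v in which(!is_fixed)) {
    # nearest dated ancestor
    s_up <- 0L; u <- v
    repeat {
      u <- parent[u]; s_up <- s_up + 1L
      if (is_fixed[u]) break
    }
    a_anc <- fixed[u]
    # nearest dated descendant (BFS through undated nodes)
    frontier <- list(c(v, 0L)); best <- NULL
    while (length(frontier)) {
      nxt <- list()
      for (f in frontier) {
        for (w in children[[as.character(f[1])]] %||% integer(0)) {
          step <- f[2] + 1L
          if (is_fixed[w]) {
            if (is.null(best) || step < best[2]) best <- c(w, step)
          } else nxt[[length(nxt) + 1L]] <- c(w, step)
        }
      }
      if (!is.null(best)) break
      frontier <- nxt
    }
    a_desc <- fixed[best[1]]; s_down <- best[2]
    age[v] <- a_anc - (a_anc - a_desc) * s_up / (s_up + s_down)
  }

  el <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(el < -1e-9))
    stop("interpolated ages imply negative branch lengths", call. = FALSE)
  tree$edge.length <- pmax(el, 0)
  tree
}

resolve_node_ids <- function(tree, nms) {
  n_tip <- ape::Ntip(tree)
  ids <- integer(length(nms))
  for (i in seq_along(nms)) {
    nm <- nms[i]
    j <- match(nm, tree$tip.label)
    if (!is.na(j)) { ids[i] <- j; next }
    if (!is.null(tree$node.label)) {
      j <- match(nm, tree$node.label)
      if (!is.na(j)) { ids[i] <- n_tip + j; next }
    }
    j <- suppressWarnings(as.integer(nm))
    if (!is.na(j) && j >= 1L && j <= n_tip + tree$Nnode) { ids[i] <- j; next }
    stop("unknown node identifier: ", nm, call. = FALSE)
  }
  ids
}
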