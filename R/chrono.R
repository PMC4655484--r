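#' Read a taxon stratigraphic-range table
#'
#' Reads a delimited text table with columns \code{taxon}, \code{fad}
#' (first-appearance age) and \code{lad} (last-appearance age), ages in Ma
#' before present (larger = older). Comma- and tab-delimited files are
#' detected automatically.
#'
#' @param path Path to a delimited text file.
#' @return A \code{data.frame} with columns \code{taxon}, \code{fad},
#'   \code{lad}, one row per taxon.
#' @export
read_taxon_ranges <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("taxon", "fad", "lad")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("range table is missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[need]
  for (col in c("fad", "lad")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric ", col, " in range table row(s): ",
           paste(bad, collapse = ", "))
    tab[[col]] <- val
  }
  validate_ranges(tab)
  tab
}

validate_ranges <- function(ranges) {
  stopifnot(all(c("taxon", "fad", "lad") %in% names(ranges)))
  bad <- which(ranges$fad < ranges$lad)
  if (length(bad))
    stop("fad < lad for row(s): ", paste(bad, collapse = ", "),
         " (", paste(ranges$taxon[bad], collapse = ", "), ")")
  bad <- which(ranges$lad < 0)
  if (length(bad))
    stop("negative lad for row(s): ", paste(bad, collapse = ", "))
  dup <- ranges$taxon[duplicated(ranges$taxon)]
  if (length(dup))
    stop("duplicate taxon name(s): ", paste(unique(dup), collapse = ", "))
  invisible(ranges)
}

#' Read a rooted tree from a Newick file
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that rejects duplicate
#' tip labels. Polytomies are permitted at this stage; resolve them with
#' \code{\link{resolve_polytomies}} before shift analysis.
#'
#' @param path Path to a Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("cannot parse Newick file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(phy)) stop("cannot parse Newick file '", path, "'")
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  phy
}

#' Randomly resolve polytomies into binary replicate topologies
#'
#' Produces \code{n_replicates} fully binary trees by random refinement of
#' every polytomy (via \code{\link[ape]{multi2di}}), reproducibly from
#' \code{seed}. A binary input yields identical copies. The replicate set
#' stands in for an MPT sample when only a consensus topology is available.
#'
#' @param phy A rooted \code{phylo}, possibly with polytomies.
#' @param n_replicates Number of replicate resolutions (>= 1).
#' @param seed Integer seed governing all resolutions.
#' @return A list of binary \code{phylo} objects of length
#'   \code{n_replicates}.
#' @export
resolve_polytomies <- function(phy, n_replicates = 10, seed = 1) {
  stopifnot(n_replicates >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  lapply(seq_len(n_replicates), function(i) ape::multi2di(phy, random = TRUE))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Time-calibrate a binary rooted topology against stratigraphic ranges
#'
#' Assigns each internal node the maximum first-appearance age (fad) among
#' its descendant tips, then expands zero-length internal branches by
#' shifting ancestors older until every internal branch has duration at
#' least \code{min_branch} (no node is ever moved younger than its base
#' age). Each terminal branch runs from its calibrated origin down to the
#' taxon's last-appearance age (lad), so the portion between branch origin
#' and fad is the taxon's ghost lineage.
#'
#' @param phy A binary rooted \code{phylo}.
#' @param ranges Range table (\code{taxon}, \code{fad}, \code{lad}) covering
#'   every tip.
#' @param min_branch Minimum internal-branch duration in Ma (>= 0,
#'   default 1).
#' @return A \code{calibrated_tree}: list with elements \code{phy} (edge
#'   lengths in Ma), \code{ages} (node ages, tips = lad) and \code{ranges}.
#' @export
calibrate <- function(phy, ranges, min_branch = 1) {
  stopifnot(inherits(phy, "phylo"), min_branch >= 0)
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("tree must be rooted and binary; resolve polytomies first")
  validate_ranges(ranges)
  missing_tips <- setdiff(phy$tip.label, ranges$taxon)
  if (length(missing_tips))
    stop("tip(s) lacking a stratigraphic range: ",
         paste(missing_tips, collapse = ", "))
  ranges <- ranges[match(phy$tip.label, ranges$taxon), , drop = FALSE]
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ages <- numeric(ntip + nnode)
  ages[seq_len(ntip)] <- ranges$lad
  fad <- ranges$fad

  po <- postorder_nodes(phy)   # internal nodes, children before parents
  kids <- children_list(phy)
  base <- numeric(ntip + nnode)
  base[seq_len(ntip)] <- fad
  for (v in po) base[v] <- max(base[kids[[v]]])
  ages[po] <- base[po]
  if (min_branch > 0) {
    for (v in po) {
      internal_kids <- kids[[v]][kids[[v]] > ntip]
      if (length(internal_kids))
        ages[v] <- max(ages[v], max(ages[internal_kids]) + min_branch)
    }
  }
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  out <- list(phy = phy, ages = ages, ranges = ranges,
              min_branch = min_branch)
  class(out) <- "calibrated_tree"
  out
}

#' @export
print.calibrated_tree <- function(x, ...) {
  if (is.null(x$phy)) {
    cat("calibrated_tree: degenerate slice with",
        length(x$tips), "lineage(s)\n")
    return(invisible(x))
  }
  ntip <- length(x$phy$tip.label)
  root_age <- x$ages[ntip + 1]
  cat("calibrated_tree:", ntip, "tips, root age",
      format(root_age, digits = 6), "Ma, span",
      format(min(x$ages), digits = 6), "-",
      format(max(x$ages), digits = 6), "Ma\n")
  invisible(x)
}

# internal nodes in an order with all children before their parent
postorder_nodes <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  unique(phy$edge[, 1])
}

children_list <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

# tip indices subtended by every node
tips_under <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  for (v in postorder_nodes(phy)) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    out[[v]] <- sort(unlist(out[ch]))
  }
  out
}

# canonical clade key: sorted tip labels
clade_key <- function(labels) paste(sort(labels), collapse = "|")
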