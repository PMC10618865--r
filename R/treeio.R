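#' Read and validate a time-calibrated tree
#'
#' Parses a Newick tree whose branch lengths are in units of time (Ma) and
#' validates it as a chronogram: tip labels must be unique and non-empty, and
#' all root-to-tip path lengths should agree (ultrametricity). Empirical
#' chronograms carry rounding error, so violations of ultrametricity beyond
#' `tol` produce a warning rather than an error.
#'
#' @param file path to a Newick file containing one tree.
#' @param text a Newick string; exactly one of `file`/`text` must be given.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an object of class `phylo` (see [ape::read.tree()]) that has passed
#'   validation; node ages can be extracted with [node_ages()].
#' @examples
#' tr <- read_timetree(text = "((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
read_timetree <- function(file = NULL, text = NULL, tol = 1e-6) {
  if (is.null(file) == is.null(text)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input", call. = FALSE)
  validate_timetree(tree, tol = tol)
  tree
}

# cheap structural scan so malformed input fails with a character offset,
# which ape's parser does not report
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input (character ",
         length(chars), ")", call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a chronogram
#'
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance.
#' @return the tree, invisibly; errors on duplicate/empty tip labels or
#'   negative branch lengths, warns if root-to-tip depths differ by more than
#'   `tol` relative to tree height.
#' @export
validate_timetree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label(s) found", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length(s)", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(labs)]
  h <- max(depths)
  if (h > 0 && (max(depths) - min(depths)) / h > tol) {
    warning("tree is not ultrametric within tolerance (max relative depth spread ",
            signif((max(depths) - min(depths)) / h, 3), ")", call. = FALSE)
  }
  invisible(tree)
}

#' Node ages of a chronogram
#'
#' Ages are measured in time units above the present (the deepest tip), so
#' tips of an ultrametric tree have age 0 and the root has the crown age.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a tibble with columns `node` (ape node number), `label` (tip label
#'   or internal node label, `NA` when absent), `is_tip`, and `age`.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  age <- max(depths) - depths
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  lab <- c(tree$tip.label,
           if (!is.null(tree$node.label)) tree$node.label else rep(NA_character_, n_node))
  length(lab) <- n_tip + n_node
  tibble::tibble(
    node = seq_len(n_tip + n_node),
    label = ifelse(nzchar(lab) & !is.na(lab), lab, NA_character_),
    is_tip = seq_len(n_tip + n_node) <= n_tip,
    age = age
  )
}

#' Prune a chronogram to a set of tips
#'
#' Returns the induced subtree on `keep`: ages of retained ancestral nodes are
#' unchanged and degree-2 nodes created by pruning are suppressed, with their
#' branch lengths summed.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_timetree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2) stop("`keep` must contain at least 2 tips", call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when writing to file.
#' @export
write_timetree <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Extract sister species pairs (cherries)
#'
#' A sister pair is two tips subtended by the same internal node, i.e. sharing
#' an ancestor unique to them. Only strictly binary cherries qualify; a
#' polytomous node with two or more tip children yields no pair (membership is
#' ambiguous) and triggers a warning. Each tip belongs to at most one pair.
#'
#' The `direct` flag marks pairs believed to be true (reciprocally
#' monophyletic) sisters as opposed to pairs that merely share an ancestor in
#' the sampled tree but may have unsampled closer relatives. Directness cannot
#' be inferred from the tree itself, so it is user-supplied metadata: pairs
#' whose two genus names both appear in `complete_genera` are marked direct,
#' all others uncertain. With `complete_genera = NULL` every pair is direct.
#'
#' @param tree a `phylo` object.
#' @param complete_genera optional character vector of genus names whose
#'   species-level sampling is complete (genus = label text before the first
#'   underscore or space).
#' @return a tibble with columns `species_a`, `species_b`, `node` (ape node
#'   number of the shared ancestor), `node_age` (Ma) and `direct` (logical).
#' @examples
#' tr <- read_timetree(text = "((A:1,B:1):1,(C:2,(D:1,E:1):1):0);")
#' sister_pairs(tr)
#' @export
sister_pairs <- function(tree, complete_genera = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) stop("tree must have at least 2 tips", call. = FALSE)
  ages <- node_ages(tree)$age
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]

  kids <- split(child, parent)
  rows <- purrr::map(names(kids), function(nd) {
    ch <- kids[[nd]]
    tip_kids <- ch[ch <= n_tip]
    if (length(ch) == 2 && length(tip_kids) == 2) {
      tibble::tibble(
        species_a = tree$tip.label[tip_kids[1]],
        species_b = tree$tip.label[tip_kids[2]],
        node = as.integer(nd),
        node_age = ages[as.integer(nd)]
      )
    } else if (length(ch) > 2 && length(tip_kids) >= 2) {
      warning("polytomy at node ", nd, " with ", length(tip_kids),
              " tip children: no sister pair extracted", call. = FALSE)
      NULL
    } else {
      NULL
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(species_a = character(), species_b = character(),
                          node = integer(), node_age = numeric(),
                          direct = logical()))
  }
  if (is.null(complete_genera)) {
    out$direct <- TRUE
  } else {
    gen <- function(x) sub("[_ ].*$", "", x)
    out$direct <- gen(out$species_a) %in% complete_genera &
      gen(out$species_b) %in% complete_genera
  }
  dplyr::arrange(out, .data$node)
}

#' Write a sister-pair table to CSV
#'
#' @param pairs tibble from [sister_pairs()].
#' @param file output path.
#' @export
write_pairs_csv <- function(pairs, file) {
  out <- dplyr::select(pairs, species_a = "species_a", species_b = "species_b",
                       node_age_ma = "node_age", direct = "direct")
  readr::write_csv(out, file)
  invisible(file)
}
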