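#' Read a time-calibrated tree
#'
#' Reads a Newick tree (branch lengths in Myr) and checks that it is
#' rooted, bifurcating and ultrametric within tolerance.
#'
#' @param path Newick file.
#' @param tol Ultrametricity tolerance as a fraction of tree depth.
#' @return An `ape::phylo`.
#' @export
read_tree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not read a tree from ", path)
  check_tree(tree, tol)
  tree
}

#' Validate an analysis tree
#'
#' @param tree An `ape::phylo`.
#' @param tol Ultrametricity tolerance as a fraction of tree depth.
#' @return The tree, invisibly; errors describe the violated requirement.
#' @export
check_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths))
    stop("tree is not ultrametric within tolerance")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @param digits Significant digits for branch lengths.
#' @export
write_tree <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Read a tip-by-character matrix
#'
#' Accepts delimited text with header `taxon,c1,...,cK` (values 0, 1 or NA)
#' or a NEXUS Characters block (detected from the `#NEXUS` magic header).
#'
#' @param path Input file.
#' @return Data frame with a `taxon` column and integer character columns.
#' @export
read_character_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
    dat <- ape::read.nexus.data(path)
    k <- length(dat[[1L]])
    m <- t(vapply(dat, function(x) {
      x[x %in% c("?", "-")] <- NA
      as.integer(x)
    }, integer(k)))
    df <- data.frame(taxon = names(dat), m, stringsAsFactors = FALSE)
    names(df)[-1L] <- paste0("c", seq_len(k))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (names(df)[1L] != "taxon")
      stop("first column of the character matrix must be `taxon`")
  }
  vals <- unlist(df[-1L])
  if (!all(is.na(vals) | vals %in% c(0L, 1L)))
    stop("character states must be 0, 1 or NA")
  df
}

#' Write a tip-by-character matrix as CSV
#'
#' @param x Data frame with `taxon` plus character columns.
#' @param path Output file.
#' @export
write_character_matrix <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a character matrix as combination states
#'
#' @param x Data frame from [read_character_matrix()].
#' @param state_space A [state_space()]; must match the column count.
#' @return Named integer vector of 0-based state indices (`NA` where any
#'   character is missing).
#' @export
states_from_matrix <- function(x, state_space) {
  k <- ncol(x) - 1L
  if (k != state_space$n_chars)
    stop(sprintf("matrix has %d characters, state space expects %d", k,
                 state_space$n_chars))
  states <- apply(as.matrix(x[-1L]), 1L, function(row) {
    if (anyNA(row)) NA_integer_ else combo_encode(row)
  })
  setNames(as.integer(states), x$taxon)
}

#' Decode combination states into a character matrix
#'
#' @param states Named integer vector of 0-based state indices.
#' @param state_space A [state_space()].
#' @return Data frame `taxon, c1, ..., cK`.
#' @export
matrix_from_states <- function(states, state_space) {
  k <- state_space$n_chars
  m <- t(vapply(states, function(s) {
    if (is.na(s)) rep(NA_integer_, k) else combo_decode(s, k)
  }, integer(k)))
  if (k == 1L) m <- matrix(m, ncol = 1L)
  df <- data.frame(taxon = names(states), m, stringsAsFactors = FALSE,
                   row.names = NULL)
  names(df)[-1L] <- paste0("c", seq_len(k))
  df
}
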