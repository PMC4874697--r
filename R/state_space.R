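#' Hypercube state space for a set of binary characters
#'
#' A set of `n_chars` binary characters is coded as a single multistate
#' character with `2^n_chars` states.  The combination string is read as a
#' binary numeral: character 1 is the leftmost position, so for three
#' characters combination `"000"` is state 0, `"001"` is state 1, `"010"` is
#' state 2, and so on.  Two states are neighbors when they differ in exactly
#' one character, giving the `n_chars`-dimensional hypercube as the
#' transition network.
#'
#' @param n_chars Number of binary characters (1 to 16).
#' @return An object of class `state_space`: a list with `n_chars`,
#'   `n_states`, `labels` (combination strings in state order) and `bits`
#'   (an `n_states` x `n_chars` 0/1 matrix, one row per state).
#' @examples
#' ss <- state_space(3)
#' ss$labels        # "000" "001" "010" ... "111"
#' combo_encode(c(0, 1, 0))  # 2
#' @export
state_space <- function(n_chars) {
  if (!is.numeric(n_chars) || length(n_chars) != 1L || n_chars < 1 ||
      n_chars > 16 || n_chars != round(n_chars))
    stop("`n_chars` must be a single integer between 1 and 16")
  n_chars <- as.integer(n_chars)
  n_states <- as.integer(2^n_chars)
  bits <- t(vapply(seq_len(n_states) - 1L, combo_decode, integer(n_chars),
                   n_chars = n_chars))
  if (n_chars == 1L) bits <- matrix(bits, ncol = 1L)
  labels <- apply(bits, 1L, paste, collapse = "")
  structure(
    list(n_chars = n_chars, n_states = n_states, labels = labels,
         bits = bits),
    class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State space: %d binary characters, %d combination states\n",
              x$n_chars, x$n_states))
  invisible(x)
}

#' Encode a binary trait combination as a state index
#'
#' @param bits Vector of 0/1 values, character 1 first.
#' @return Integer state index in `[0, 2^length(bits))`.
#' @export
combo_encode <- function(bits) {
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0, 1)))
    stop("combination must be a vector of 0/1 values")
  k <- length(bits)
  as.integer(sum(bits * 2^(k - seq_len(k))))
}

#' Decode a state index into its binary trait combination
#'
#' @param state Integer state index.
#' @param n_chars Number of characters.
#' @return Integer 0/1 vector of length `n_chars`, character 1 first.
#' @export
combo_decode <- function(state, n_chars) {
  if (state < 0 || state >= 2^n_chars || state != round(state))
    stop("state index out of range")
  as.integer(bitwAnd(bitwShiftR(as.integer(state),
                                n_chars - seq_len(n_chars)), 1L))
}

#' Neighboring states on the hypercube
#'
#' @param state Integer state index.
#' @param state_space A [state_space()].
#' @return Integer vector of the `n_chars` states differing from `state` in
#'   exactly one character.
#' @export
combo_neighbors <- function(state, state_space) {
  if (state < 0 || state >= state_space$n_states || state != round(state))
    stop("state index out of range")
  sort(bitwXor(as.integer(state),
               2L^(seq_len(state_space$n_chars) - 1L)))
}

#' Enumerate focal-area bipartition masks
#'
#' Every division of the combination network into a focal set F and its
#' complement N is described by a mask string over `{0, 1, *}`: a state is
#' focal when it matches the mask at every non-`*` position.  The all-`*`
#' mask (F = everything) is excluded, leaving `3^n_chars - 1` masks: 728 for
#' six characters.
#'
#' @param state_space A [state_space()].
#' @return Character vector of masks in a deterministic order.
#' @export
enumerate_bipartitions <- function(state_space) {
  k <- state_space$n_chars
  digits <- c("0", "1", "*")
  grid <- expand.grid(rep(list(digits), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; flip so the leftmost
  # character is the slowest digit, giving lexicographic mask order
  masks <- apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste,
                 collapse = "")
  masks <- sort(masks[masks != strrep("*", k)])
  masks
}

#' States in the focal set of a mask
#'
#' @param mask Mask string over `{0, 1, *}`, one position per character.
#' @param state_space A [state_space()].
#' @return Integer vector of focal state indices; `2^(number of *)` states.
#' @export
focal_members <- function(mask, state_space) {
  m <- check_mask(mask, state_space$n_chars)
  fixed <- which(m != "*")
  if (length(fixed) == 0L) return(seq_len(state_space$n_states) - 1L)
  want <- as.integer(m[fixed])
  hit <- apply(state_space$bits[, fixed, drop = FALSE], 1L,
               function(row) all(row == want))
  which(hit) - 1L
}

check_mask <- function(mask, n_chars) {
  if (!is.character(mask) || length(mask) != 1L || nchar(mask) != n_chars)
    stop(sprintf("mask must be a single string of length %d", n_chars))
  m <- strsplit(mask, "")[[1L]]
  if (!all(m %in% c("0", "1", "*")))
    stop("mask may contain only '0', '1' and '*'")
  m
}

#' Drop bipartitions with an empty side among the observed states
#'
#' Combinations not represented by any sampled species cannot constitute a
#' viable set; a bipartition is retained only when at least one observed
#' state falls on each side.
#'
#' @param masks Character vector of bipartition masks.
#' @param observed_states Integer vector of observed state indices.
#' @param state_space A [state_space()].
#' @return The viable subset of `masks`.
#' @export
filter_viable <- function(masks, observed_states, state_space) {
  if (length(observed_states) == 0L || anyNA(observed_states))
    stop("`observed_states` must be a non-empty vector of state indices")
  obs <- unique(as.integer(observed_states))
  keep <- vapply(masks, function(mk) {
    f <- focal_members(mk, state_space)
    n_f <- sum(obs %in% f)
    n_f > 0L && n_f < length(obs)
  }, logical(1L))
  unname(masks[keep])
}

#' Number of free parameters
#'
#' For the full multistate model every directed hypercube edge carries its
#' own transition rate and every state its own speciation and extinction
#' rate: `(n_chars + 2) * 2^n_chars` parameters, i.e. 512 for six characters
#' (384 transition, 64 speciation, 64 extinction).  With
#' `directed = FALSE` each undirected edge carries one rate
#' (`n_chars * 2^(n_chars - 1)` transition parameters; 12 at three
#' characters).  For a tied bipartition model the count is the sum of the
#' transition-family and diversification-family parameter counts (at most
#' 4 + 4 = 8).
#'
#' @param spec Either the string `"full"` or a list with elements
#'   `transition` and `diversification` naming registry models (see
#'   [transition_models()], [diversification_models()]).
#' @param state_space A [state_space()].
#' @param directed For `"full"`: one rate per directed edge (default) or per
#'   undirected edge.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, state_space, directed = TRUE) {
  k <- state_space$n_chars
  if (identical(spec, "full")) {
    n_q <- if (directed) k * 2^k else k * 2^(k - 1)
    return(as.integer(n_q + 2 * 2^k))
  }
  tm <- transition_models()[[spec$transition]]
  dm <- diversification_models()[[spec$diversification]]
  if (is.null(tm) || is.null(dm)) stop("unknown model identifier")
  as.integer(tm$n_par + dm$n_par)
}
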