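# Deterministic avoidance automaton over S-dangerous strings.
#
# A string is S-dangerous if it is empty or a proper prefix of a forbidden
# pattern.  The automaton's states are exactly the dangerous strings; the
# transition delta(q, a) is the longest dangerous suffix of q.a, or FORBIDDEN
# when q.a has a pattern as a suffix (conceptually, the transition enters the
# merged forbidden trie node, which is deleted from the final object).
# FORBIDDEN transitions are encoded as state id 0.

#' Sentinel state id for forbidden transitions
#'
#' @seealso [automaton_run()], [prefix_automaton()]
#' @export
FORBIDDEN <- 0L

#' Build the forbidden-pattern avoidance automaton
#'
#' Constructs the complete deterministic automaton whose states are the
#' S-dangerous strings (the empty string plus every proper prefix of a
#' pattern in `patterns`).  The trie of the patterns is turned into an
#' automaton with a breadth-first computation of the failure function
#' `f(q)` (longest proper dangerous suffix of `q`) and the transition
#' function `delta(q, a)` (`q.a` itself when `q.a` is dangerous, otherwise
#' `delta(f(q), a)`); transitions that would complete a pattern are marked
#' [FORBIDDEN].  Walking the automaton from the root therefore tracks, for
#' any text, its longest dangerous suffix, and hits [FORBIDDEN] exactly when
#' the text acquires a forbidden pattern as a substring.
#'
#' @param patterns A [pattern_set()] (or character vector, normalized on the
#'   fly).
#' @param alphabet Optional [alphabet()]; defaults to the pattern set's.
#' @return An object of class `prefix_automaton` with elements `states`
#'   (character; `states[1]` is the empty string), `delta` (integer matrix,
#'   states x letters, `0` = FORBIDDEN), `fail`, `depth`, `alphabet`,
#'   `patterns`.
#' @examples
#' A <- prefix_automaton(pattern_set(c("bbbb", "abba", "aaba")))
#' length(A$states)        # 9 dangerous strings
#' sum(A$delta == FORBIDDEN)
#' @export
prefix_automaton <- function(patterns, alphabet = NULL) {
  S <- as_pattern_set(patterns, alphabet)
  ab <- if (is.null(alphabet)) attr(S, "alphabet") else as_alphabet(alphabet)
  letters <- unclass(ab)
  sigma <- length(letters)
  pats <- as.character(S)

  if (length(pats) == 0L) {
    A <- list(states = "", delta = matrix(1L, 1L, sigma), fail = 1L,
              depth = 0L, max_depth = 0L, sigma = sigma,
              alphabet = ab, patterns = S,
              nonsink_map = list(), max_suffix = 0L)
    class(A) <- "prefix_automaton"
    return(A)
  }

  lens <- nchar(pats)
  states <- unique(unlist(lapply(pats, function(p) {
    substring(p, 1L, 0:(nchar(p) - 1L))
  })))
  states <- states[order(nchar(states), states, method = "radix")]
  n <- length(states)
  depth <- nchar(states)

  parent_id <- rep(NA_integer_, n)
  in_letter <- rep(NA_integer_, n)
  nz <- which(depth > 0L)
  parent_id[nz] <- match(substr(states[nz], 1L, depth[nz] - 1L), states)
  in_letter[nz] <- match(substr(states[nz], depth[nz], depth[nz]), letters)

  delta <- matrix(NA_integer_, n, sigma)
  delta[cbind(parent_id[nz], in_letter[nz])] <- nz

  # transitions completing a full pattern are forbidden (they would enter the
  # merged forbidden node, which is deleted)
  forb_state <- match(substr(pats, 1L, lens - 1L), states)
  forb_letter <- match(substr(pats, lens, lens), letters)
  delta[cbind(forb_state, forb_letter)] <- 0L

  fail <- rep(1L, n)
  # root: any letter that is neither a trie child nor a length-1 pattern
  # stays at the empty string
  delta[1L, is.na(delta[1L, ])] <- 1L

  for (lev in seq_len(max(depth))) {
    W <- which(depth == lev)
    if (lev == 1L) {
      fail[W] <- 1L
    } else {
      fail[W] <- delta[cbind(fail[parent_id[W]], in_letter[W])]
      # anti-factoriality guarantees the failure target is dangerous, never
      # the forbidden node
      stopifnot(all(fail[W] > 0L))
    }
    for (a in seq_len(sigma)) {
      miss <- W[is.na(delta[W, a])]
      if (length(miss)) delta[miss, a] <- delta[cbind(fail[miss], a)]
    }
  }

  # complementary-prefix index: for pattern s = q.p (p a proper suffix),
  # nonsink_map[[p]] lists the state ids q; used to locate non-sink states
  # for a given right context v
  suf_keys <- character(0)
  q_ids <- integer(0)
  multi <- which(lens > 1L)
  if (length(multi)) {
    pieces <- lapply(multi, function(i) {
      m <- lens[i]
      ell <- seq_len(m - 1L)
      list(suf = substring(pats[i], m - ell + 1L, m),
           q = match(substring(pats[i], 1L, m - ell), states))
    })
    suf_keys <- unlist(lapply(pieces, `[[`, "suf"))
    q_ids <- unlist(lapply(pieces, `[[`, "q"))
  }
  nonsink_map <- split(q_ids, suf_keys)

  A <- list(states = states, delta = delta, fail = fail, depth = depth,
            max_depth = max(depth), sigma = sigma, alphabet = ab,
            patterns = S, nonsink_map = nonsink_map,
            max_suffix = max(lens) - 1L)
  class(A) <- "prefix_automaton"
  A
}

#' @export
print.prefix_automaton <- function(x, ...) {
  cat(sprintf(
    "<prefix_automaton> %d states over {%s}; %d forbidden transition(s)\n",
    length(x$states), paste(unclass(x$alphabet), collapse = ","),
    sum(x$delta == 0L)))
  invisible(x)
}

#' Run the automaton over a string
#'
#' Follows `delta` letter by letter from `from` (the root, i.e. the empty
#' string, by default).  Returns the id of the state reached, or [FORBIDDEN]
#' (`0`) as soon as any transition is forbidden — which happens exactly when
#' the text spelled so far contains a forbidden pattern.
#'
#' @param A A [prefix_automaton()].
#' @param s String to spell (over the automaton's alphabet).
#' @param from Starting state id (default 1, the empty string).
#' @return Integer state id, or `FORBIDDEN` (0).
#' @export
automaton_run <- function(A, s, from = 1L) {
  stopifnot(inherits(A, "prefix_automaton"))
  if (!nzchar(s)) return(as.integer(from))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ranks <- match(chars, unclass(A$alphabet))
  if (anyNA(ranks)) {
    ss_abort("unknown_letter", "string contains letters outside the alphabet: %s",
             paste(unique(chars[is.na(ranks)]), collapse = ", "))
  }
  q <- as.integer(from)
  for (r in ranks) {
    q <- A$delta[q, r]
    if (q == 0L) return(FORBIDDEN)
  }
  q
}

#' State labels of an automaton
#'
#' @param A A [prefix_automaton()].
#' @param ids Optional state ids; all states by default.
#' @return Character vector of dangerous strings.
#' @export
automaton_states <- function(A, ids = NULL) {
  if (is.null(ids)) A$states else A$states[ids]
}

# Internal: ids of the states q for which some pattern s = q.p has a
# nonempty prefix p of v as its suffix (the "marked" complementary
# prefixes, before closure under the failure function).
marked_non_sinks <- function(A, v) {
  if (A$max_suffix == 0L || !nzchar(v)) return(integer(0))
  ells <- seq_len(min(nchar(v), A$max_suffix))
  ids <- unlist(A$nonsink_map[substring(v, 1L, ells)], use.names = FALSE)
  unique(ids)
}

# Internal: given marked ids, decide non-sinkness for arbitrary state ids by
# walking failure chains (a state is unsafe iff any dangerous suffix of it is
# marked).
nonsink_flags <- function(A, ids, marked_logical) {
  bad <- marked_logical[ids]
  cur <- A$fail[ids]
  for (i in seq_len(A$max_depth)) {
    bad <- bad | marked_logical[cur]
    cur <- A$fail[cur]
  }
  bad
}

#' Non-sink states for a right context
#'
#' A state `q` is a *non-sink* for the right context `v` when appending `v`
#' to any text whose longest dangerous suffix is `q` would create an
#' occurrence of a forbidden pattern, i.e. when `q.v` contains a pattern.
#' These are located by matching every nonempty prefix of `v` against the
#' suffixes of the patterns (each match marks the complementary pattern
#' prefix) and then closing the marked set under the failure function: a
#' state ending with a marked state is unsafe too.
#'
#' @param A A [prefix_automaton()].
#' @param v Right context; must itself be free of forbidden patterns.
#' @return Sorted integer vector of non-sink state ids, named with the state
#'   strings.  Every other state is a sink.
#' @export
non_sink_states <- function(A, v) {
  stopifnot(inherits(A, "prefix_automaton"))
  if (nzchar(v) && automaton_run(A, v) == FORBIDDEN) {
    ss_abort("infeasible_context",
             "a forbidden pattern occurs in the right context")
  }
  marked <- logical(length(A$states))
  marked[marked_non_sinks(A, v)] <- TRUE
  if (!any(marked)) return(structure(integer(0), names = character(0)))
  flags <- nonsink_flags(A, seq_along(A$states), marked)
  ids <- which(flags)
  names(ids) <- A$states[ids]
  ids
}
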