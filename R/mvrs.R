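# Missing value replacement in strings (MVRS): shortest x with prefix u,
# suffix v, avoiding every forbidden pattern.

has_pattern <- function(x, patterns) {
  if (length(patterns) == 0L) return(rep(FALSE, length(x)))
  Reduce(`|`, lapply(as.character(patterns), grepl, x = x, fixed = TRUE))
}

#' Suffix/prefix overlap lengths of two strings
#'
#' All lengths `l >= 1` such that the length-`l` suffix of `u` equals the
#' length-`l` prefix of `v`, in decreasing order.  These are the candidate
#' merge points for a replacement string no longer than `|u| + |v|`.
#'
#' @param u,v Strings.
#' @return Integer vector of overlap lengths, decreasing (possibly empty).
#' @examples
#' suffix_prefix_overlaps("aab", "aba")   # 2
#' suffix_prefix_overlaps("abab", "abab") # 4 2
#' @export
suffix_prefix_overlaps <- function(u, v) {
  m <- min(nchar(u), nchar(v))
  if (m == 0L) return(integer(0))
  ells <- seq_len(m)
  hit <- substring(u, nchar(u) - ells + 1L, nchar(u)) == substring(v, 1L, ells)
  sort(ells[hit], decreasing = TRUE)
}

mvrs_result <- function(status, x = NA_character_, middle = NA_character_,
                        overlap_used = NA_integer_, reason = NA_character_) {
  structure(list(status = status, x = x, middle = middle,
                 overlap_used = overlap_used, reason = reason),
            class = "mvrs_result")
}

#' @export
print.mvrs_result <- function(x, ...) {
  if (x$status == "SOLVED") {
    cat(sprintf("<mvrs> SOLVED: \"%s\" (|x| = %d%s)\n", x$x, nchar(x$x),
                if (!is.na(x$overlap_used))
                  sprintf(", overlap %d", x$overlap_used)
                else sprintf(", middle \"%s\"", x$middle)))
  } else {
    cat(sprintf("<mvrs> FAIL (%s)\n", x$reason))
  }
  invisible(x)
}

# Internal: breadth-first search from `source` to the nearest sink over
# non-forbidden transitions.  Frontiers are kept in lexicographic order of
# their (unique, shortest) spellings and letters are expanded in rank order,
# so the first sink reached yields the lexicographically smallest shortest
# middle string.  Returns the letter-rank path, or NULL if no sink is
# reachable.
bfs_middle <- function(A, source, marked_logical) {
  if (nonsink_flags(A, source, marked_logical) == FALSE) return(integer(0))
  n <- length(A$states)
  visited <- logical(n)
  visited[source] <- TRUE
  parent <- integer(n)
  parent_letter <- integer(n)
  frontier <- source
  repeat {
    tr <- A$delta[frontier, , drop = FALSE]
    cand <- as.vector(t(tr))                       # parent-major, letter-minor
    par <- rep(frontier, each = A$sigma)
    lets <- rep.int(seq_len(A$sigma), length(frontier))
    ok <- cand != 0L
    ok[ok] <- !visited[cand[ok]]
    idx <- which(ok)
    if (length(idx) == 0L) return(NULL)
    first <- !duplicated(cand[idx])
    idx <- idx[first]
    new <- cand[idx]
    parent[new] <- par[idx]
    parent_letter[new] <- lets[idx]
    visited[new] <- TRUE
    sinks <- !nonsink_flags(A, new, marked_logical)
    if (any(sinks)) {
      q <- new[which(sinks)[1]]
      path <- integer(0)
      while (q != source) {
        path <- c(parent_letter[q], path)
        q <- parent[q]
      }
      return(path)
    }
    frontier <- new
  }
}

#' Solve the missing value replacement problem
#'
#' Finds a shortest string `x` such that `u` is a prefix of `x`, `v` is a
#' suffix of `x`, and no forbidden pattern occurs in `x`; or reports FAIL if
#' no such string exists.  The search runs on the avoidance automaton
#' ([prefix_automaton()]): first the overlap case (`|x| <= |u| + |v|`),
#' where `u` is spelled from the root and, at each position reached in a
#' sink state, the corresponding suffix/prefix overlap is accepted (longest
#' overlap first); then the general case, a breadth-first search from the
#' state reached after `u` to the nearest sink, whose path spells the
#' inserted middle `h` and gives `x = u h v` (with `h` empty when the source
#' is itself a sink).  Among equally short solutions the lexicographically
#' smallest middle (in alphabet rank order) is returned, so results are
#' reproducible.
#'
#' @param u,v Left and right context (either may be empty).
#' @param patterns Forbidden patterns ([pattern_set()] or character vector).
#' @param alphabet Optional [alphabet()]; inferred from `u`, `v` and the
#'   patterns when `NULL`.
#' @param automaton Optional prebuilt [prefix_automaton()] for `patterns`
#'   (reuse it across many instances sharing one antidictionary).
#' @return An `mvrs_result`: list with `status` (`"SOLVED"` or `"FAIL"`),
#'   `x`, `middle` (the inserted fragment, `""` in the overlap case),
#'   `overlap_used` (overlap length when the overlap case applied, else
#'   `NA`), and `reason` (`"PATTERN_IN_CONTEXT"` or `"NO_PATH"` on FAIL).
#' @examples
#' solve_mvrs("aab", "aba", c("bbbb", "abba", "aaba"))$x  # "aabbbaba"
#' solve_mvrs("a", "b", c("aa", "ab"), alphabet("ab"))$status  # FAIL
#' @export
solve_mvrs <- function(u, v, patterns, alphabet = NULL, automaton = NULL) {
  if (!is.null(automaton)) {
    stopifnot(inherits(automaton, "prefix_automaton"))
    A <- automaton
    ab <- A$alphabet
  } else {
    ab <- as_alphabet(alphabet, infer_from = c(u, v, as.character(patterns)))
    S <- as_pattern_set(patterns, ab)
    A <- prefix_automaton(S, ab)
  }
  check_over_alphabet(u, ab, "the left context")
  check_over_alphabet(v, ab, "the right context")

  if (automaton_run(A, u) == FORBIDDEN || automaton_run(A, v) == FORBIDDEN) {
    return(mvrs_result("FAIL", reason = "PATTERN_IN_CONTEXT"))
  }

  marked <- logical(length(A$states))
  marked[marked_non_sinks(A, v)] <- TRUE

  # states along u: q_path[i + 1] is the state after spelling u[1..i]
  nu <- nchar(u)
  q_path <- integer(nu + 1L)
  q_path[1L] <- 1L
  if (nu > 0L) {
    ranks <- match(strsplit(u, "", fixed = TRUE)[[1]], unclass(ab))
    for (i in seq_len(nu)) q_path[i + 1L] <- A$delta[q_path[i], ranks[i]]
  }

  # Case 1: |x| <= |u| + |v| via a nonempty suffix/prefix overlap
  overlaps <- suffix_prefix_overlaps(u, v)
  if (length(overlaps)) {
    sinks_along <- !nonsink_flags(A, q_path, marked)
    for (ell in overlaps) {             # longest overlap = shortest x first
      i <- nu - ell
      if (sinks_along[i + 1L]) {
        return(mvrs_result("SOLVED", x = paste0(substr(u, 1L, i), v),
                           middle = "", overlap_used = ell))
      }
    }
  }

  # Case 2: |x| >= |u| + |v|, breadth-first search to the nearest sink
  path <- bfs_middle(A, q_path[nu + 1L], marked)
  if (is.null(path)) {
    return(mvrs_result("FAIL", reason = "NO_PATH"))
  }
  h <- paste(unclass(ab)[path], collapse = "")
  mvrs_result("SOLVED", x = paste0(u, h, v), middle = h)
}

# lexicographic enumeration of all strings of length m over `letters`
# (leftmost position most significant)
all_strings <- function(letters, m) {
  out <- ""
  for (i in seq_len(m)) out <- paste0(rep(out, each = length(letters)), letters)
  out
}

#' Exhaustive-search oracle for MVRS
#'
#' Enumerates candidate strings in increasing length (then lexicographically
#' by alphabet rank) and returns the first feasible one.  Candidates shorter
#' than `|u| + |v|` are the overlap merges of `u` and `v`; longer candidates
#' are `u h v` for every middle `h` in rank order (any string with prefix
#' `u` and suffix `v` has one of these two forms).  Intended as an
#' independent test oracle for [solve_mvrs()] on small instances.
#'
#' @inheritParams solve_mvrs
#' @param max_len Maximum candidate length before giving up with FAIL.
#' @param budget Maximum number of candidate strings to examine.
#' @return An `mvrs_result` (as for [solve_mvrs()]; `middle`/`overlap_used`
#'   are filled in analogously).
#' @export
mvrs_brute_force <- function(u, v, patterns, alphabet = NULL, max_len = 14L,
                             budget = 2e6) {
  ab <- as_alphabet(alphabet, infer_from = c(u, v, as.character(patterns)))
  S <- as_pattern_set(patterns, ab)
  check_over_alphabet(u, ab, "the left context")
  check_over_alphabet(v, ab, "the right context")
  letters <- unclass(ab)
  nu <- nchar(u); nv <- nchar(v)
  examined <- 0
  if (max(nu, nv) > max_len) return(mvrs_result("FAIL", reason = "NO_PATH"))
  for (n in seq(max(nu, nv), max_len)) {
    if (n < nu + nv) {
      ell <- nu + nv - n
      if (ell > min(nu, nv)) next
      if (substring(u, nu - ell + 1L, nu) != substring(v, 1L, ell)) next
      x <- paste0(substr(u, 1L, nu - ell), v)
      examined <- examined + 1
      if (!has_pattern(x, S)) {
        return(mvrs_result("SOLVED", x = x, middle = "", overlap_used = ell))
      }
    } else {
      m <- n - nu - nv
      n_cand <- length(letters)^m
      examined <- examined + n_cand
      if (examined > budget) {
        ss_abort("oracle_budget",
                 "brute-force search space exceeds the budget of %g candidates",
                 budget)
      }
      mids <- all_strings(letters, m)
      cands <- paste0(u, mids, v)
      feas <- !has_pattern(cands, S)
      if (any(feas)) {
        i <- which(feas)[1]
        return(mvrs_result("SOLVED", x = cands[i], middle = mids[i]))
      }
    }
  }
  mvrs_result("FAIL", reason = "NO_PATH")
}
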