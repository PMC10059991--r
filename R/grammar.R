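#' Parse a BNF grammar
#'
#' Accepts the usual grammatical-evolution BNF dialect: one rule per line
#' (`<sym> ::= alt | alt | ...`), angle-bracketed nonterminals, literal
#' terminal text, `|`-separated alternatives, and continuation lines that
#' extend the previous rule.  Production order is preserved — the
#' genotype-to-phenotype mapping depends on it.
#'
#' @param text Grammar source, a character vector of lines or one string.
#' @return Object of class `"ge_grammar"`: nonterminal table, productions
#'   (integer-encoded: positive = nonterminal index, negative = terminal
#'   index), and the minimum derivation-tree depth of every nonterminal
#'   and production (used by the grow initialiser).
#' @examples
#' g <- parse_grammar("<e> ::= <e>+<e> | x | y")
#' length(g$rules[[1]]) # 3 productions
#' @export
parse_grammar <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rules_raw <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("::=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "::=", fixed = TRUE)[[1]]
      lhs <- trimws(parts[1])
      if (!grepl("^<[^<>]+>$", lhs))
        stop("bad rule head: ", lhs, call. = FALSE)
      current <- lhs
      rhs <- paste(parts[-1], collapse = "::=")
      rules_raw[[current]] <- c(rules_raw[[current]], rhs)
    } else {
      if (is.null(current)) stop("continuation line before any rule",
                                 call. = FALSE)
      rules_raw[[current]] <- c(rules_raw[[current]], ln)
    }
  }
  if (length(rules_raw) == 0L) stop("empty grammar", call. = FALSE)
  nts <- names(rules_raw)
  terminals <- character(0)
  term_id <- function(s) {
    i <- match(s, terminals)
    if (is.na(i)) { terminals[length(terminals) + 1L] <<- s
                    i <- length(terminals) }
    -i
  }
  split_tokens <- function(alt) {
    toks <- integer(0)
    while (nzchar(alt)) {
      m <- regexpr("<[^<>]+>", alt)
      if (m == -1L) { toks <- c(toks, term_id(alt)); break }
      if (m > 1L) toks <- c(toks, term_id(substr(alt, 1L, m - 1L)))
      nt <- substr(alt, m, m + attr(m, "match.length") - 1L)
      j <- match(nt, nts)
      if (is.na(j)) stop("undefined nonterminal ", nt, call. = FALSE)
      toks <- c(toks, j)
      alt <- substr(alt, m + attr(m, "match.length"), nchar(alt))
    }
    toks
  }
  rules <- vector("list", length(nts))
  for (i in seq_along(nts)) {
    alts <- unlist(strsplit(paste(rules_raw[[i]], collapse = " "),
                            "|", fixed = TRUE))
    alts <- trimws(alts)
    alts <- alts[nzchar(alts)]
    if (length(alts) == 0L)
      stop("nonterminal ", nts[i], " has no productions", call. = FALSE)
    rules[[i]] <- lapply(alts, split_tokens)
  }
  g <- structure(list(nonterminals = nts, rules = rules,
                      terminals = terminals, start = 1L),
                 class = "ge_grammar")
  .grammar_depths(g)
}

# minimum derivation depth per nonterminal / production (fixpoint)
.grammar_depths <- function(g) {
  n <- length(g$nonterminals)
  d <- rep(Inf, n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      best <- Inf
      for (p in g$rules[[i]]) {
        nt <- p[p > 0]
        pd <- if (length(nt) == 0L) 1 else 1 + max(d[nt])
        best <- min(best, pd)
      }
      if (best < d[i]) { d[i] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  if (any(!is.finite(d)))
    stop("grammar has nonterminal(s) with no finite derivation: ",
         paste(g$nonterminals[!is.finite(d)], collapse = ", "), call. = FALSE)
  g$min_depth <- d
  g$prod_min_depth <- lapply(seq_len(n), function(i)
    vapply(g$rules[[i]], function(p) {
      nt <- p[p > 0]
      if (length(nt) == 0L) 1 else 1 + max(d[nt])
    }, numeric(1L)))
  g
}

#' @export
print.ge_grammar <- function(x, ...) {
  cat("ge_grammar:", length(x$nonterminals), "nonterminals,",
      sum(lengths(x$rules)), "productions, start", x$nonterminals[x$start],
      "\n")
  invisible(x)
}

#' The glucose forecasting grammar
#'
#' Generates exactly the four-block model shape
#' `(Gamma(G) - Theta(I) + Omega(C)) op Phi(dG)` with `op` in `{+, -, *}`:
#' a glucose-history block, minus an insulin block, plus a carbohydrate
#' block, combined with a glucose-difference block.  Each block is an
#' arithmetic expression (`+`, `-`, `*`, protected `plog`, `psqrt`, `aq`,
#' digit-built constants) over its own variable set only: past glucose
#' `g0..g<k>`, future insulin `i0..i<h>`, future carbohydrates `c0..c<h>`,
#' and backward differences `dg1..dg<k>`.  Composite subexpressions are
#' parenthesised so the printed formula parses unambiguously.
#'
#' @param k Past-window length (default 12): variables `g0..gk`, `dg1..dgk`.
#' @param h Forecast horizon (default 6): variables `i0..ih`, `c0..ch`.
#' @return A `"ge_grammar"`.
#' @export
glucose_grammar <- function(k = 12, h = 6) {
  vars <- function(prefix, idx) paste(paste0(prefix, idx), collapse = " | ")
  block <- function(name, var_nt) sprintf(
    "<%s> ::= (<%s><op><%s>) | plog(<%s>) | psqrt(<%s>) | aq(<%s>,<%s>) | <%s> | <const>",
    name, name, name, name, name, name, name, var_nt)
  txt <- c(
    "<expr> ::= (<gexpr>-<iexpr>+<cexpr>)<op><dgexpr>",
    "<op> ::= + | - | *",
    block("gexpr", "gvar"),
    block("iexpr", "ivar"),
    block("cexpr", "cvar"),
    block("dgexpr", "dgvar"),
    paste("<gvar> ::=", vars("g", 0:k)),
    paste("<ivar> ::=", vars("i", 0:h)),
    paste("<cvar> ::=", vars("c", 0:h)),
    paste("<dgvar> ::=", vars("dg", 1:k)),
    "<const> ::= <digit>.<digit> | <digit>",
    "<digit> ::= 0 | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 | 9")
  parse_grammar(txt)
}

#' Map a codon genome to a phenotype expression
#'
#' Standard grammatical-evolution leftmost-derivation mapping: each
#' expansion of a nonterminal with `m` productions consumes one codon `c`
#' and selects production `c mod m`.  When the genome is exhausted it is
#' reused from the start up to `max_wraps` times; a derivation that still
#' holds nonterminals after that (or that exceeds `max_nodes` expansions)
#' is invalid — a value, not an error.
#'
#' @param genome Integer vector of codons in `[0, codon_size)`.
#' @param grammar A `"ge_grammar"`.
#' @param max_wraps Times the genome may be reread (default 2).
#' @param max_nodes Expansion budget guarding against runaway derivations.
#' @return List with `valid` (logical), `phenotype` (string or `NA`), and
#'   `used` (codons consumed, capped at the genome length).
#' @examples
#' g <- parse_grammar("<e> ::= <e>+<e> | x | y")
#' map_genome(c(3, 4, 8), g)$phenotype # "x+y"
#' @export
map_genome <- function(genome, grammar, max_wraps = 2, max_nodes = 5000L) {
  stopifnot(inherits(grammar, "ge_grammar"))
  len <- length(genome)
  if (len == 0L) stop("empty genome", call. = FALSE)
  limit <- (max_wraps + 1L) * len
  rules <- grammar$rules
  stack <- integer(256L); stack[1L] <- grammar$start; top <- 1L
  out <- character(0)
  ci <- 0L
  nodes <- 0L
  while (top > 0L) {
    sym <- stack[top]; top <- top - 1L
    if (sym < 0L) { out[length(out) + 1L] <- grammar$terminals[-sym]; next }
    nodes <- nodes + 1L
    if (nodes > max_nodes)
      return(list(valid = FALSE, phenotype = NA_character_, used = len))
    prods <- rules[[sym]]
    m <- length(prods)
    if (ci >= limit)
      return(list(valid = FALSE, phenotype = NA_character_, used = len))
    codon <- genome[(ci %% len) + 1L]
    ci <- ci + 1L
    p <- prods[[(codon %% m) + 1L]]
    # push tokens reversed so the leftmost symbol is processed next
    np <- length(p)
    if (top + np > length(stack)) stack <- c(stack, integer(length(stack)))
    if (np > 0L) { stack[(top + 1L):(top + np)] <- rev(p); top <- top + np }
  }
  list(valid = TRUE, phenotype = paste0(out, collapse = ""),
       used = min(ci, len))
}

#' Grow-style random genome initialisation
#'
#' Builds a random derivation tree of bounded depth — at each nonterminal a
#' production is drawn uniformly among those completable within the
#' remaining depth budget (falling back to a minimum-depth production when
#' none fits) — and serialises it to codons in leftmost order, each codon
#' drawn uniformly from the values congruent to the chosen production
#' index.  Every generated genome therefore maps to a valid phenotype of
#' depth at most `max_depth`.
#'
#' @param grammar A `"ge_grammar"`.
#' @param max_depth Maximum derivation-tree depth (default 10).
#' @param codon_size Exclusive codon upper bound (default 100000).
#' @return Integer codon vector.
#' @export
grow_genome <- function(grammar, max_depth = 10, codon_size = 100000L) {
  codons <- integer(0)
  emit <- function(choice, m) {
    c0 <- choice - 1L
    jmax <- (codon_size - 1L - c0) %/% m
    codons[[length(codons) + 1L]] <<- c0 + m * sample.int(jmax + 1L, 1L) - m
  }
  expand <- function(nt, budget) {
    pmd <- grammar$prod_min_depth[[nt]]
    feasible <- which(pmd <= budget)
    if (length(feasible) == 0L) feasible <- which(pmd == min(pmd))
    choice <- feasible[sample.int(length(feasible), 1L)]
    emit(choice, length(grammar$rules[[nt]]))
    for (tok in grammar$rules[[nt]][[choice]])
      if (tok > 0L) expand(tok, budget - 1L)
  }
  expand(grammar$start, max_depth)
  codons
}
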