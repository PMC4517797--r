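#' Read a single-word entity lexicon
#'
#' Lexicons list one surface term per line (UTF-8). Only single-word terms are
#' usable for entity matching, because only those map to single nodes of a
#' sentence dependency graph: multi-word entries (for example
#' `"IL-1 receptor"`) are rejected at load time with a warning and can never be
#' matched. Terms are case-folded, so matching is case-insensitive. An optional
#' stoplist of common-English words removes promiscuous terms such as gene
#' symbols that are also ordinary words (for example `"CAT"`).
#'
#' @param path File with one term per line. Blank lines are ignored.
#' @param stoplist Optional character vector (or file path when
#'   `stoplist_is_file = TRUE`) of common-English words to remove, compared
#'   case-insensitively.
#' @param stoplist_is_file Interpret `stoplist` as a path to a one-term-per-line
#'   file.
#' @return A character vector of unique, case-folded single-word terms.
#' @export
read_lexicon <- function(path, stoplist = NULL, stoplist_is_file = FALSE) {
  terms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  multi <- grepl("\\s", terms)
  if (any(multi)) {
    warn(sprintf(
      "Dropped %d multi-word lexicon entr%s (only single-word names are matchable), e.g. \"%s\".",
      sum(multi), if (sum(multi) == 1) "y" else "ies", terms[multi][1]
    ))
    terms <- terms[!multi]
  }
  terms <- unique(tolower(terms))
  if (stoplist_is_file) {
    stoplist <- readLines(stoplist, encoding = "UTF-8", warn = FALSE)
  }
  if (!is.null(stoplist)) {
    terms <- setdiff(terms, tolower(trimws(stoplist)))
  }
  terms
}

#' Read dependency graphs from a CoNLL-like TSV file
#'
#' Each sentence is a block of lines `token_index<TAB>word<TAB>governor_index
#' <TAB>relation`, with blank lines separating sentences. Token indices are
#' 1-based; a governor index of 0 marks the root (no edge is created for it).
#'
#' @param path TSV file as described above.
#' @return A list of dependency graphs; each is a list with `tokens`
#'   (character vector in token order) and `edges` (a tibble with columns
#'   `governor`, `dependent`, `relation`).
#' @export
read_dependency_graphs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  graphs <- list()
  for (g in split(lines[!blank], grp[!blank])) {
    fields <- strsplit(g, "\t", fixed = TRUE)
    bad <- vapply(fields, length, 0L) < 4
    if (any(bad)) {
      stop_ebclust("Malformed dependency-graph line: expected 4 tab-separated fields.",
                   "ebclust_parse_error")
    }
    idx <- as.integer(vapply(fields, `[[`, "", 1))
    word <- vapply(fields, `[[`, "", 2)
    gov <- as.integer(vapply(fields, `[[`, "", 3))
    rel <- vapply(fields, `[[`, "", 4)
    ord <- order(idx)
    has_gov <- gov[ord] > 0
    graphs[[length(graphs) + 1]] <- dependency_graph(
      tokens = word[ord],
      edges = tibble(
        governor = gov[ord][has_gov],
        dependent = idx[ord][has_gov],
        relation = rel[ord][has_gov]
      )
    )
  }
  graphs
}

#' Construct a dependency graph
#'
#' @param tokens Character vector of sentence tokens in order.
#' @param edges Tibble or data frame with integer columns `governor` and
#'   `dependent` (1-based token indices) and a character `relation` column.
#' @return An object of class `ebc_dependency_graph`.
#' @export
dependency_graph <- function(tokens, edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("governor", "dependent", "relation") %in% names(edges)))
  if (any(!nzchar(edges$relation))) {
    stop_ebclust("Relation labels must be non-empty strings.", "ebclust_bad_graph")
  }
  structure(list(tokens = tokens, edges = edges),
            class = "ebc_dependency_graph")
}

#' Sentence-length eligibility window
#'
#' Sentences are eligible for path extraction when they contain between 4 and
#' 50 tokens inclusive; this keeps roughly 95% of corpus sentences while
#' excluding fragments and run-ons that parse poorly.
#'
#' @param token_count Non-negative integer vector of sentence lengths.
#' @return Logical vector.
#' @export
eligible_sentence <- function(token_count) {
  token_count >= 4 & token_count <= 50
}

#' Match drug and gene mentions in a dependency graph
#'
#' Simple string matching of each token against the two lexicons, after
#' case-folding both sides. A token present in both lexicons yields one mention
#' per entity class. Lexicons must contain single-word terms only (see
#' [read_lexicon()]).
#'
#' @param graph An `ebc_dependency_graph`.
#' @param drug_lexicon,gene_lexicon Character vectors of single-word terms.
#' @return A tibble with columns `surface`, `token` (index), `class`
#'   (`"drug"` or `"gene"`), and `term` (the lexicon entry matched). Empty when
#'   nothing matches.
#' @export
match_entities <- function(graph, drug_lexicon, gene_lexicon) {
  folded <- tolower(graph$tokens)
  hit <- function(lexicon, class) {
    i <- which(folded %in% tolower(lexicon))
    tibble(surface = graph$tokens[i], token = i, class = class, term = folded[i])
  }
  dplyr::bind_rows(hit(drug_lexicon, "drug"), hit(gene_lexicon, "gene"))
}

# Unique tree path between two token indices; returns integer node sequence or
# signals a structural error when the endpoints are disconnected or the walk
# revisits a node (non-tree input).
tree_path <- function(edges, from, to, n_tokens) {
  if (nrow(edges) != n_tokens - 1) {
    stop_ebclust(
      sprintf("Dependency graph is not a tree: %d tokens but %d edges.",
              n_tokens, nrow(edges)),
      "ebclust_structural_error"
    )
  }
  adj <- vector("list", n_tokens)
  for (e in seq_len(nrow(edges))) {
    a <- edges$governor[e]; b <- edges$dependent[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # BFS recording parents
  parent <- rep(NA_integer_, n_tokens)
  seen <- rep(FALSE, n_tokens)
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[to]) {
    stop_ebclust("Dependency graph is disconnected between the two mentions.",
                 "ebclust_structural_error")
  }
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

#' Extract the drug-to-gene dependency path between two mentions
#'
#' Returns the unique tree path between the drug and gene tokens, oriented from
#' the drug to the gene with edge directions discarded and the endpoint tokens
#' themselves dropped. The result alternates relation labels and interior
#' words, serialised as a canonical pipe-delimited string (relations
#' lower-cased, interior words case-folded), e.g. `"appos|inhibitor|amod"`.
#'
#' Paths containing any dependency whose label starts with `conj` (such as
#' `conj_and`) are rejected — these mostly reflect parser treatment of lists,
#' not true relationships — and `NA_character_` is returned. Structural
#' problems (non-tree graph, disconnected mentions) raise an error instead, so
#' callers can distinguish filtering from malformed input.
#'
#' @param graph An `ebc_dependency_graph`.
#' @param drug_token,gene_token Token indices (1-based) of the two mentions.
#' @return Canonical path string, or `NA_character_` for a conj rejection.
#' @export
extract_path <- function(graph, drug_token, gene_token) {
  n_tokens <- length(graph$tokens)
  nodes <- tree_path(graph$edges, drug_token, gene_token, n_tokens)
  # relation for each consecutive node pair, direction-free
  key <- paste(pmin(graph$edges$governor, graph$edges$dependent),
               pmax(graph$edges$governor, graph$edges$dependent))
  rel_of <- setNames(graph$edges$relation, key)
  rels <- character(length(nodes) - 1)
  for (i in seq_along(rels)) {
    rels[i] <- rel_of[[paste(min(nodes[i], nodes[i + 1]),
                             max(nodes[i], nodes[i + 1]))]]
  }
  if (any(startsWith(tolower(rels), "conj"))) {
    return(NA_character_)
  }
  interior <- tolower(graph$tokens[nodes[-c(1, length(nodes))]])
  elements <- character(0)
  for (i in seq_along(rels)) {
    elements <- c(elements, tolower(rels[i]))
    if (i < length(rels)) elements <- c(elements, interior[i])
  }
  paste(elements, collapse = "|")
}

#' Extract aggregated drug-gene dependency paths from a parsed corpus
#'
#' Runs entity matching and path extraction over a list of sentence dependency
#' graphs, applying the sentence-length eligibility window and the conj filter,
#' and aggregates identical (drug, gene, path) triplets into occurrence counts.
#' A sentence with `d` drug and `g` gene mentions contributes at most `d * g`
#' paths. Tokens matching both lexicons are used in both roles, but a mention
#' is never paired with itself.
#'
#' @param graphs List of `ebc_dependency_graph` objects (see
#'   [read_dependency_graphs()]).
#' @param drug_lexicon,gene_lexicon Character vectors of single-word terms.
#' @return A tibble of triplet records with columns `drug`, `gene`, `path`,
#'   `count`, sorted by decreasing count.
#' @export
extract_paths <- function(graphs, drug_lexicon, gene_lexicon) {
  rows <- purrr::map(graphs, function(graph) {
    if (!eligible_sentence(length(graph$tokens))) return(NULL)
    mentions <- match_entities(graph, drug_lexicon, gene_lexicon)
    drugs <- mentions[mentions$class == "drug", ]
    genes <- mentions[mentions$class == "gene", ]
    if (nrow(drugs) == 0 || nrow(genes) == 0) return(NULL)
    combos <- tidyr::expand_grid(d = seq_len(nrow(drugs)), g = seq_len(nrow(genes)))
    out <- purrr::pmap(combos, function(d, g) {
      if (drugs$token[d] == genes$token[g]) return(NULL)
      p <- extract_path(graph, drugs$token[d], genes$token[g])
      if (is.na(p)) return(NULL)
      tibble(drug = drugs$term[d], gene = genes$term[g], path = p)
    })
    dplyr::bind_rows(out)
  })
  triplets <- dplyr::bind_rows(rows)
  if (nrow(triplets) == 0) {
    return(tibble(drug = character(), gene = character(),
                  path = character(), count = integer()))
  }
  triplets |>
    dplyr::count(.data$drug, .data$gene, .data$path, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$drug, .data$gene, .data$path)
}
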