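#' Construct a GO-style term universe
#'
#' Holds a directed acyclic graph of terms (is_a edges), term names and
#' namespaces, and a gene-to-term annotation table that is closed under
#' ancestors (a gene annotated to a term is annotated to every ancestral
#' term). Cyclic graphs are rejected.
#'
#' @param terms data.frame with columns id, name, namespace.
#' @param parents Named list: term id -> character vector of parent term
#'   ids (empty for roots).
#' @param annotation data.frame with columns gene, term (direct
#'   annotations; ancestral closure is applied here).
#' @return Object of class `go_universe` with elements `terms`, `parents`,
#'   `annotation` (closed), `gene2terms` (named list).
#' @export
go_universe <- function(terms, parents, annotation) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("gene", "term") %in% names(annotation)))
  parents <- parents[terms$id[terms$id %in% names(parents)]]
  missing <- setdiff(terms$id, names(parents))
  parents[missing] <- list(character())
  # acyclicity via Kahn's algorithm
  indeg <- vapply(parents, length, integer(1))
  order_seen <- 0L
  queue <- names(indeg)[indeg == 0]
  indeg_work <- indeg
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  while (length(queue)) {
    t0 <- queue[1]; queue <- queue[-1]; order_seen <- order_seen + 1L
    for (ch in children[[t0]] %||% character()) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (order_seen < length(parents)) stop("term graph contains a cycle")

  anc_cache <- go_ancestor_table(parents)
  closed <- unique(data.frame(
    gene = rep(annotation$gene, lengths(anc_cache[annotation$term])),
    term = unlist(anc_cache[annotation$term], use.names = FALSE),
    stringsAsFactors = FALSE))
  structure(list(terms = as.data.frame(terms), parents = parents,
                 ancestors = anc_cache, annotation = closed,
                 gene2terms = split(closed$term, closed$gene)),
            class = "go_universe")
}

# term -> all ancestors including self
go_ancestor_table <- function(parents) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t0) {
    if (!is.null(memo[[t0]])) return(memo[[t0]])
    ps <- parents[[t0]] %||% character()
    res <- unique(c(t0, unlist(lapply(ps, get_anc), use.names = FALSE)))
    memo[[t0]] <- res
    res
  }
  out <- lapply(names(parents), get_anc)
  names(out) <- names(parents)
  out
}

#' Hypergeometric GO over-representation test
#'
#' For each term, tests whether the foreground gene set is enriched for
#' the term's genes relative to the background, with an upper-tail
#' hypergeometric p-value and Benjamini-Hochberg correction across all
#' tested terms. Terms are tested when they annotate at least one
#' background gene.
#'
#' @param foreground Character vector of genes (must be a subset of
#'   `background`).
#' @param background Character vector of genes defining the universe N.
#' @param universe A [go_universe()].
#' @param direction Label carried into the output ("up", "down", "both").
#' @param fdr_max Terms with q below this are flagged `enriched`
#'   (default 0.01).
#' @return data.frame: term, name, namespace, k (foreground hits),
#'   n (foreground size), K (term size in background), N, ratio (k/K),
#'   p, q, enriched; sorted by p.
#' @export
hypergeom_enrich <- function(foreground, background, universe,
                             direction = "both", fdr_max = 0.01) {
  if (length(foreground) == 0)
    return(data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), ratio = numeric(),
                      p = numeric(), q = numeric(), enriched = logical(),
                      direction = character()))
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  ann <- universe$annotation[universe$annotation$gene %in% background, ]
  N <- length(unique(background))
  n <- length(unique(foreground))
  Kt <- table(ann$term)
  kt <- table(ann$term[ann$gene %in% foreground])
  terms <- names(Kt)
  k <- as.integer(kt[terms]); k[is.na(k)] <- 0L
  K <- as.integer(Kt[terms])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  info <- universe$terms[match(terms, universe$terms$id), ]
  out <- data.frame(term = terms, name = info$name,
                    namespace = info$namespace,
                    k = k, n = n, K = K, N = N, ratio = k / K,
                    p = p, q = q, enriched = q < fdr_max,
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Information-content semantic similarity between terms
#'
#' Lin similarity: 2*IC(MICA)/(IC(t1)+IC(t2)), where IC(t) =
#' -log(frequency of t in the ancestor-closed annotation corpus) and MICA
#' is the most informative common ancestor. Resnik (IC of the MICA) is
#' also available. Terms whose ICs are both zero (roots) have similarity 1
#' if identical, else 0.
#'
#' @param terms Character vector of term ids.
#' @param universe A [go_universe()].
#' @param measure "lin" (default) or "resnik".
#' @return Symmetric similarity matrix.
#' @export
term_similarity <- function(terms, universe, measure = c("lin", "resnik")) {
  measure <- match.arg(measure)
  ann <- universe$annotation
  n_genes <- length(unique(ann$gene))
  freq <- table(ann$term) / n_genes
  ic <- -log(as.numeric(freq))
  names(ic) <- names(freq)
  ic_of <- function(t0) if (t0 %in% names(ic)) ic[[t0]] else Inf
  anc <- universe$ancestors
  m <- matrix(0, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (i in seq_along(terms)) {
    for (j in i:length(terms)) {
      common <- intersect(anc[[terms[i]]], anc[[terms[j]]])
      ic_mica <- if (length(common)) {
        max(vapply(common, ic_of, numeric(1))[is.finite(
          vapply(common, ic_of, numeric(1)))], 0)
      } else 0
      s <- if (measure == "resnik") {
        ic_mica
      } else {
        denom <- ic_of(terms[i]) + ic_of(terms[j])
        if (!is.finite(denom) || denom <= 0) {
          if (terms[i] == terms[j]) 1 else 0
        } else 2 * ic_mica / denom
      }
      m[i, j] <- m[j, i] <- s
    }
  }
  diag(m) <- if (measure == "resnik") diag(m) else 1
  m
}

#' Collapse enriched terms to representatives by semantic similarity
#'
#' Pools enrichment results across runs (condition x direction), groups
#' terms within each namespace by single-linkage clustering at similarity
#' strictly greater than `similarity_min`, and reports one representative
#' per group: the member with the maximum enrichment ratio across all
#' runs. Per representative, `minq` is the smallest q-value and `maxRatio`
#' the largest enrichment ratio attained by any group member in any run.
#'
#' @param results data.frame concatenating [hypergeom_enrich()] outputs
#'   (columns term, name, namespace, ratio, q at minimum).
#' @param universe A [go_universe()].
#' @param similarity_min Similarity threshold (default 0.5; strict).
#' @param measure Passed to [term_similarity()].
#' @return data.frame: term, namespace, name, minq, maxRatio, group_size.
#' @export
semantic_collapse <- function(results, universe, similarity_min = 0.5,
                              measure = "lin") {
  known <- results$term %in% universe$terms$id
  if (any(!known)) {
    message(sprintf("semantic_collapse: %d term(s) absent from the DAG",
                    sum(!known)))
    results <- results[known, ]
  }
  if (nrow(results) == 0) return(results)
  out <- list()
  for (ns in unique(results$namespace)) {
    rs <- results[results$namespace == ns, ]
    terms <- unique(rs$term)
    if (length(terms) == 1) {
      grp <- stats::setNames(1L, terms)
    } else {
      sim <- term_similarity(terms, universe, measure = measure)
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
      grp <- stats::cutree(hc, h = 1 - similarity_min - 1e-9)
    }
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      sub <- rs[rs$term %in% members, ]
      rep_term <- sub$term[which.max(sub$ratio)]
      out[[length(out) + 1]] <- data.frame(
        term = rep_term, namespace = ns,
        name = sub$name[sub$term == rep_term][1],
        minq = min(sub$q), maxRatio = max(sub$ratio),
        group_size = length(members), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$maxRatio), ]
  rownames(res) <- NULL
  res
}

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' fields into the pieces needed by [go_universe()].
#'
#' @param path OBO file path.
#' @return List with `terms` (data.frame) and `parents` (named list).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  terms <- list(); parents <- list()
  bounds <- c(idx, length(lines) + 1)
  for (i in seq_along(idx)) {
    block <- lines[idx[i]:(bounds[i + 1] - 1)]
    get1 <- function(tag) sub(paste0("^", tag, ": "), "",
                              grep(paste0("^", tag, ": "), block, value = TRUE))
    first_or <- function(x, default) if (length(x)) x[1] else default
    id <- get1("id")[1]
    terms[[i]] <- data.frame(id = id, name = first_or(get1("name"), id),
                             namespace = first_or(get1("namespace"), "BP"),
                             stringsAsFactors = FALSE)
    parents[[id]] <- sub(" !.*$", "", get1("is_a"))
  }
  list(terms = do.call(rbind, terms), parents = parents)
}

#' Write a term universe as an OBO file
#'
#' @param universe A [go_universe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(universe, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(universe$terms))) {
    t0 <- universe$terms[i, ]
    writeLines(c("[Term]",
                 paste0("id: ", t0$id),
                 paste0("name: ", t0$name),
                 paste0("namespace: ", t0$namespace),
                 paste0("is_a: ", universe$parents[[t0$id]]),
                 ""), con)
  }
  invisible(path)
}
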