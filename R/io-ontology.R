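#' Gene Ontology graph container
#'
#' Holds a directed acyclic graph of ontology terms (child-to-parent
#' `is_a`/`part_of` edges), the namespace of each term, the depth of each
#' term (length of the longest path to its namespace root, root = 0) and,
#' once [compute_ic()] has been applied, the information content of each
#' term.
#'
#' @param terms Character vector of term IDs.
#' @param parents Named list mapping each term to a character vector of
#'   parent term IDs (empty for roots).
#' @param namespace Named character vector giving each term's namespace.
#' @return An object of class `go_graph` with elements `terms`, `parents`,
#'   `children`, `namespace`, `depth`, `ancestors` (each term's ancestor
#'   set, itself included) and `ic` (NA until [compute_ic()]).
#' @export
go_graph <- function(terms, parents, namespace) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term IDs")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p))
  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, terms)
  if (length(unknown))
    stop("parent term(s) not defined: ", paste(unknown, collapse = ", "))
  namespace <- namespace[terms]
  for (t in terms) {
    bad <- parents[[t]][namespace[parents[[t]]] != namespace[t]]
    if (length(bad))
      stop("term ", t, " has parent(s) in a different namespace")
  }
  edges <- data.frame(
    child = rep(terms, lengths(parents)),
    parent = unlist(parents, use.names = FALSE),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) stop("cycle detected in ontology graph")

  # ancestors (self included) along child -> parent edges
  ancestors <- lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
  names(ancestors) <- terms

  # depth = longest path from the term down from its namespace root,
  # computed over a topological order (parents before children)
  ord <- names(igraph::topo_sort(g, mode = "in"))
  depth <- setNames(rep(0L, length(terms)), terms)
  for (t in ord) {
    p <- parents[[t]]
    if (length(p)) depth[t] <- max(depth[p]) + 1L
  }

  children <- split(edges$child, factor(edges$parent, levels = terms))
  structure(list(terms = terms, parents = parents, children = children,
                 namespace = namespace, depth = depth,
                 ancestors = ancestors,
                 ic = setNames(rep(NA_real_, length(terms)), terms)),
            class = "go_graph")
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms, namespaces: %s, IC %s\n",
              length(x$terms),
              paste(unique(x$namespace), collapse = "/"),
              if (anyNA(x$ic)) "not computed" else "computed"))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `namespace`, `is_a` and
#' `relationship: part_of` lines; obsolete terms are skipped and other
#' relationship types ignored.  Depths are computed on load; information
#' content requires a companion annotation map (see [compute_ic()]).
#'
#' @param path Path to an OBO file.
#' @return A [go_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  ids <- character(); ns <- character(); parents <- list()
  cur <- NULL; cur_ns <- NA_character_; cur_par <- character()
  obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (in_term && !obsolete && !is.null(cur)) {
      ids[[length(ids) + 1L]] <<- cur
      ns[[length(ns) + 1L]] <<- cur_ns
      parents[[cur]] <<- cur_par
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]" || ln == "[Typedef]") {
      flush()
      in_term <- ln == "[Term]"
      cur <- NULL; cur_ns <- NA_character_
      cur_par <- character(); obsolete <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "namespace:")) {
        cur_ns <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur_par <- c(cur_par, tgt)
      } else if (startsWith(ln, "relationship:")) {
        rest <- trimws(sub("^relationship:", "", ln))
        if (startsWith(rest, "part_of")) {
          tgt <- trimws(sub("!.*$", "", sub("^part_of", "", rest)))
          cur_par <- c(cur_par, tgt)
        }
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  if (!length(ids)) stop("no terms found in OBO file")
  ns[is.na(ns)] <- "biological_process"
  go_graph(ids, parents, setNames(ns, ids))
}

#' Read a gene-to-GO annotation map
#'
#' Accepts either a two-column TSV (`gene_id<TAB>GO:ID`) or GAF 2.x
#' (columns 2 and 5, comment lines starting with `!`).  Terms absent from
#' the companion graph are dropped with a warning; genes left with no
#' terms are not stored.
#'
#' @param path Path to the annotation file.
#' @param go A [go_graph()] the term IDs must belong to.
#' @param format `"tsv"` or `"gaf"`.
#' @return A named list mapping gene ID to a character vector of term IDs.
#' @export
read_annotations <- function(path, go, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    genes <- vapply(parts, `[[`, character(1L), 2L)
    terms <- vapply(parts, `[[`, character(1L), 5L)
  } else {
    lines <- lines[!startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    genes <- vapply(parts, `[[`, character(1L), 1L)
    terms <- vapply(parts, `[[`, character(1L), 2L)
  }
  known <- terms %in% go$terms
  if (!all(known)) {
    warning(sum(!known), " annotation row(s) with unknown term dropped")
    genes <- genes[known]; terms <- terms[known]
  }
  ann <- lapply(split(terms, genes), unique)
  ann[lengths(ann) > 0L]
}

#' Write an annotation map as two-column TSV
#' @param ann Named list gene -> term IDs.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(gene_id = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compute per-term information content from annotation usage
#'
#' `IC(t) = -log p(t)` (natural log) with `p(t)` the fraction of annotated
#' genes annotated to `t` or any of its descendants.  Terms never used,
#' directly or via descendants, receive the IC of the rarest used term so
#' that similarity formulas remain defined.
#'
#' @param go A [go_graph()].
#' @param ann An annotation map from [read_annotations()].
#' @return The graph with its `ic` field filled.
#' @export
compute_ic <- function(go, ann) {
  total <- length(ann)
  if (total == 0L) stop("empty annotation map")
  counts <- setNames(rep(0L, length(go$terms)), go$terms)
  for (terms in ann) {
    anc <- unique(unlist(go$ancestors[terms], use.names = FALSE))
    counts[anc] <- counts[anc] + 1L
  }
  ic <- -log(counts / total)
  used <- is.finite(ic)
  if (!any(used)) stop("no annotated term maps into the graph")
  ic[!used] <- max(ic[used])
  go$ic <- ic
  go
}
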