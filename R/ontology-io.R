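.OBO_NAMESPACES <- c(
  molecular_function = "MF",
  biological_process = "BP",
  cellular_component = "CC"
)

# Assemble a validated GeneOntology from parallel per-term vectors/lists.
.makeOntology <- function(ids, names_, namespaces, parents, altIds = character()) {
  names(names_) <- ids
  names(namespaces) <- ids
  names(parents) <- ids
  # drop cross-aspect and dangling parent edges
  parents <- lapply(ids, function(id) {
    ps <- unique(parents[[id]])
    ps <- ps[ps %in% ids]
    ps[namespaces[ps] == namespaces[[id]] & ps != id]
  })
  names(parents) <- ids
  children <- lapply(ids, function(id) character(0))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children <- lapply(children, function(x) sort(unique(x)))
  roots <- character(0)
  for (asp in unique(namespaces)) {
    inAsp <- ids[namespaces[ids] == asp]
    parentless <- inAsp[lengths(parents[inAsp]) == 0L]
    if (length(parentless) != 1L) {
      stop(sprintf(
        "aspect %s must have exactly one root term, found %d (%s)",
        asp, length(parentless), paste(head(parentless, 4), collapse = ", ")),
        call. = FALSE)
    }
    roots[[asp]] <- parentless
  }
  new("GeneOntology", termIds = ids, termName = names_,
      namespace = namespaces, parents = parents, children = children,
      roots = roots, altIds = altIds)
}

#' Read a Gene Ontology DAG from an OBO file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping `is_a` and
#' (optionally) `relationship: part_of` edges. Obsolete terms are dropped,
#' cross-aspect edges are filtered out, and `alt_id` accessions are recorded
#' so that annotation readers can remap them to the canonical accession.
#'
#' @param path path to the OBO file.
#' @param partOf include `part_of` relationship edges as parents (default
#'   `TRUE`, matching the usual GOA propagation convention).
#' @return A [GeneOntology-class] object.
#' @examples
#' obo <- generateDag(syntheticConfig(nTerms = 10, seed = 1))
#' f <- tempfile(fileext = ".obo"); writeOBO(obo, f)
#' readOBO(f)
#' @export
readOBO <- function(path, partOf = TRUE) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stanzaStart <- grep("^\\[", lines)
  termStart <- grep("^\\[Term\\]$", trimws(lines))
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list(); altIds <- character(0)
  for (s in termStart) {
    nxt <- stanzaStart[stanzaStart > s]
    endLine <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):endLine]
    block <- block[nzchar(trimws(block))]
    block <- block[!grepl("^!", trimws(block))]
    kvOk <- grepl("^[A-Za-z_]+:", trimws(block))
    if (any(!kvOk)) {
      badAt <- s + which(!kvOk)[1]
      stop(sprintf("malformed OBO stanza near line %d: '%s'",
                   badAt, trimws(lines[badAt])), call. = FALSE)
    }
    getv <- function(key) {
      hit <- grep(sprintf("^%s:", key), trimws(block), value = TRUE)
      trimws(sub("!.*$", "", sub(sprintf("^%s:", key), "", trimws(hit))))
    }
    if (length(getv("is_obsolete")) && any(getv("is_obsolete") == "true")) next
    id <- getv("id")
    if (length(id) != 1L) {
      stop(sprintf("OBO stanza starting at line %d lacks a unique id", s),
           call. = FALSE)
    }
    ns <- getv("namespace")
    if (!length(ns)) {
      stop(sprintf("term %s (line %d) lacks a namespace", id, s), call. = FALSE)
    }
    nsShort <- if (ns %in% GO_ASPECTS) ns else .OBO_NAMESPACES[[ns]]
    if (is.null(nsShort) || is.na(nsShort)) {
      stop(sprintf("unknown namespace '%s' for %s", ns, id), call. = FALSE)
    }
    ps <- sub(" .*$", "", getv("is_a"))
    if (partOf) {
      rel <- getv("relationship")
      po <- rel[grepl("^part_of ", rel)]
      ps <- c(ps, sub("^part_of +", "", po))
      ps <- sub(" .*$", "", ps)
    }
    for (alt in getv("alt_id")) altIds[[alt]] <- id
    ids <- c(ids, id)
    nmv <- getv("name")
    nms <- c(nms, if (length(nmv)) nmv[1] else id)
    nss <- c(nss, nsShort)
    parents[[id]] <- unique(ps)
  }
  if (!length(ids)) stop("no usable [Term] stanzas in ", path, call. = FALSE)
  dag <- .makeOntology(ids, nms, nss, parents[ids], altIds)
  validObject(dag)
  dag
}

#' Serialize a GeneOntology to OBO format
#'
#' Writes a minimal OBO 1.2 document (`is_a` edges only; `part_of` parents
#' recorded in the object are emitted as `is_a` since the internal graph does
#' not distinguish them once parsed).
#'
#' @param dag a [GeneOntology-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  long <- setNames(names(.OBO_NAMESPACES), .OBO_NAMESPACES)
  for (id in goTerms(dag)) {
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", id), con)
    writeLines(sprintf("name: %s", dag@termName[[id]]), con)
    writeLines(sprintf("namespace: %s", long[[dag@namespace[[id]]]]), con)
    for (p in dag@parents[[id]]) writeLines(sprintf("is_a: %s", p), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Default experimental evidence codes for GAF filtering
#'
#' The eight evidence codes regarded as experimental when selecting reliable
#' annotations: EXP, IDA, IPI, IMP, IGI, IEP, TAS and IC.
#' @export
experimentalEvidenceCodes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")
}

.GAF_ASPECT <- c(F = "MF", P = "BP", C = "CC")

#' Read annotations from a GAF 2.1/2.2 file
#'
#' Uses columns 2 (protein ID), 4 (qualifier), 5 (GO ID), 7 (evidence code)
#' and 9 (aspect). Rows whose qualifier contains `NOT`, whose evidence code
#' is outside `evidence`, or whose aspect differs from `aspect` are dropped.
#'
#' @param path GAF file ("!"-prefixed header lines are skipped).
#' @param aspect which GO aspect to keep.
#' @param evidence evidence-code whitelist; default the eight experimental
#'   codes of [experimentalEvidenceCodes()].
#' @return An unpropagated [GOAnnotationSet-class].
#' @export
readGAF <- function(path, aspect = c("BP", "MF", "CC"),
                    evidence = experimentalEvidenceCodes()) {
  aspect <- match.arg(aspect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(GOAnnotationSet(list(), aspect = aspect))
  }
  tab <- read.delim(text = lines, header = FALSE, quote = "",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 9L) stop("GAF file must have >= 9 columns", call. = FALSE)
  keep <- !grepl("NOT", tab[[4]]) &
    tab[[7]] %in% evidence &
    .GAF_ASPECT[as.character(tab[[9]])] %in% aspect
  keep[is.na(keep)] <- FALSE
  tab <- tab[keep, , drop = FALSE]
  GOAnnotationSet(data.frame(protein = tab[[2]], term = tab[[5]]),
                  aspect = aspect)
}

#' Read annotations from a plain two-column TSV (protein, GO term)
#'
#' @param path TSV with protein IDs in column 1 and GO accessions in column
#'   2; no header.
#' @param aspect GO aspect tag to attach.
#' @return An unpropagated [GOAnnotationSet-class].
#' @export
readAnnotationsTSV <- function(path, aspect = c("BP", "MF", "CC")) {
  aspect <- match.arg(aspect)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  GOAnnotationSet(data.frame(protein = tab[[1]], term = tab[[2]]),
                  aspect = aspect)
}

#' Write annotations as a two-column TSV
#'
#' @param anno a [GOAnnotationSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationsTSV <- function(anno, path) {
  a <- annotations(anno)
  df <- data.frame(
    protein = rep(names(a), lengths(a)),
    term = unlist(a, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
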