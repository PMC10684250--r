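#' @include AllClasses.R accessors.R
NULL

readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, warn = FALSE)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and lines starting with \code{#} are skipped; symbols are
#' upper-cased and deduplicated preserving first-seen order.
#'
#' @param path path to a text file with one gene symbol per line.
#' @return character vector of unique upper-case gene symbols.
#' @examples
#' f <- tempfile(); writeLines(c("tp53", "TP53", "BRCA1"), f)
#' readGeneList(f)
#' @export
readGeneList <- function(path) {
  ln <- trimws(readLinesChecked(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("no usable lines in gene list: ", path, call. = FALSE)
  unique(toupper(ln))
}

#' Write a gene list
#'
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(c("# gene", genes), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' \code{id <TAB> description <TAB> gene <TAB> gene ...}. Genes within a row
#' are upper-cased and deduplicated; duplicate set ids are an error.
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdemo\tA\tB\tB", f)
#' setSizes(readGmt(f))
#' @export
readGmt <- function(path) {
  ln <- readLinesChecked(path)
  keep <- nzchar(trimws(ln))
  ln <- ln[keep]; lineno <- which(keep)
  if (!length(ln))
    return(new("GeneSetCollection", setIds = character(),
               descriptions = character(), members = list()))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  ids <- character(length(parts)); desc <- character(length(parts))
  members <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    genes <- if (length(f) >= 3) f[-(1:2)][nzchar(f[-(1:2)])] else character()
    if (length(f) < 3 || !length(genes))
      stop(sprintf("GMT format error at line %d: need id, description and >=1 gene",
                   lineno[i]), call. = FALSE)
    ids[i] <- f[1]; desc[i] <- f[2]
    members[[i]] <- unique(toupper(genes))
  }
  if (anyDuplicated(ids))
    stop("duplicate set id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  new("GeneSetCollection", setIds = ids, descriptions = desc,
      members = members)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  ln <- vapply(seq_along(gsc@setIds), function(i)
    paste(c(gsc@setIds[i], gsc@descriptions[i], gsc@members[[i]]),
          collapse = "\t"), character(1))
  writeLines(ln, path)
  invisible(path)
}

#' Read a regulator-target map from a two-column TSV
#'
#' Each non-comment line is one \code{regulator <TAB> gene} pair. Duplicate
#' pairs are collapsed (a message reports how many), genes are upper-cased,
#' and miRNA regulator ids are lower-cased.
#'
#' @param path path to the TSV file.
#' @param regulatorClass \code{"miRNA"} or \code{"drug"}.
#' @param header logical; skip the first non-comment line if \code{TRUE}.
#' @return a [TargetMap-class].
#' @examples
#' f <- tempfile(); writeLines(c("m1\tA", "m1\tA", "m1\tB"), f)
#' targetsOf(readTargetMap(f, "miRNA"), "m1")
#' @export
readTargetMap <- function(path, regulatorClass = c("miRNA", "drug"),
                          header = FALSE) {
  regulatorClass <- match.arg(regulatorClass)
  ln <- readLinesChecked(path)
  keep <- nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")
  ln <- ln[keep]; lineno <- which(keep)
  if (header && length(ln)) { ln <- ln[-1]; lineno <- lineno[-1] }
  if (!length(ln))
    return(new("TargetMap", targets = stats::setNames(list(), character()),
               regulatorClass = regulatorClass))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("target map format error at line %d: expected 2 tab-separated columns",
                 lineno[bad[1]]), call. = FALSE)
  reg <- vapply(parts, `[[`, character(1), 1L)
  gene <- toupper(vapply(parts, `[[`, character(1), 2L))
  if (regulatorClass == "miRNA") reg <- tolower(reg)
  ndup <- sum(duplicated(paste0(reg, "\r", gene)))
  if (ndup) message("collapsed ", ndup, " duplicate (regulator, gene) pair(s)")
  targets <- lapply(split(gene, reg), unique)
  # split() sorts keys; restore first-seen regulator order
  targets <- targets[unique(reg)]
  new("TargetMap", targets = targets, regulatorClass = regulatorClass)
}

#' Write a regulator-target map as a two-column TSV
#'
#' @param tm a [TargetMap-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTargetMap <- function(tm, path) {
  stopifnot(is(tm, "TargetMap"))
  ln <- unlist(lapply(names(tm@targets), function(r)
    paste(r, tm@targets[[r]], sep = "\t")), use.names = FALSE)
  writeLines(c("# regulator\tgene", ln), path)
  invisible(path)
}

#' Restrict gene sets or target maps to a gene universe
#'
#' Removes every member gene not present in \code{universe}. Sets or target
#' lists left empty are retained, and a message reports both the number of
#' removed symbols and the ids of emptied sets.
#'
#' @param x a [GeneSetCollection-class] or [TargetMap-class].
#' @param universe non-empty character vector of gene symbols (upper-cased
#'   before matching).
#' @return an object of the same class as \code{x}.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = c("A", "B", "C")))
#' setSizes(restrictToUniverse(gsc, c("A", "B")))
#' @export
setGeneric("restrictToUniverse",
           function(x, universe) standardGeneric("restrictToUniverse"))

restrictList <- function(sets, universe, what) {
  out <- lapply(sets, function(m) m[m %in% universe])
  removed <- sum(lengths(sets)) - sum(lengths(out))
  if (removed)
    message("restrictToUniverse: removed ", removed, " symbol(s) outside the universe")
  emptied <- names(sets)[lengths(out) == 0L & lengths(sets) > 0L]
  if (length(emptied))
    message("restrictToUniverse: ", length(emptied), " ", what,
            " left empty: ", paste(utils::head(emptied, 5), collapse = ", "))
  out
}

#' @rdname restrictToUniverse
#' @export
setMethod("restrictToUniverse", "GeneSetCollection", function(x, universe) {
  stopifnot(length(universe) > 0)
  universe <- toupper(universe)
  sets <- stats::setNames(x@members, x@setIds)
  x@members <- unname(restrictList(sets, universe, "set(s)"))
  x
})

#' @rdname restrictToUniverse
#' @export
setMethod("restrictToUniverse", "TargetMap", function(x, universe) {
  stopifnot(length(universe) > 0)
  universe <- toupper(universe)
  x@targets <- restrictList(x@targets, universe, "target set(s)")
  x
})

sifRelation <- c(miRNA = "regulates", drug = "targets_pathway")

#' Write an MDNG as a SIF edge file
#'
#' One edge per line, \code{source <TAB> relation <TAB> target}, in
#' deterministic lexicographic order. Relations are \code{regulates} for
#' miRNA-pathway edges and \code{targets_pathway} for drug-pathway edges;
#' node names keep their class prefix so a round trip through [readSif()]
#' reproduces the edge set exactly.
#'
#' @param network an [Mdng-class].
#' @param path output path.
#' @return the path, invisibly.
#' @seealso [readSif()]
#' @export
writeSif <- function(network, path) {
  stopifnot(is(network, "Mdng"))
  g <- network@graph
  header <- "# source\trelation\ttarget"
  if (!igraph::ecount(g)) { writeLines(header, path); return(invisible(path)) }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  cls <- igraph::V(g)$class; nm <- igraph::V(g)$name
  regFirst <- cls[ends[, 1]] != "pathway"
  src <- ifelse(regFirst, nm[ends[, 1]], nm[ends[, 2]])
  dst <- ifelse(regFirst, nm[ends[, 2]], nm[ends[, 1]])
  rel <- sifRelation[ifelse(regFirst, cls[ends[, 1]], cls[ends[, 2]])]
  ln <- sort(paste(src, rel, dst, sep = "\t"))
  writeLines(c(header, ln), path)
  invisible(path)
}

#' Read an MDNG from a SIF edge file
#'
#' Accepts the files produced by [writeSif()]: node classes are recovered
#' from the class prefix of each name (or, failing that, from the relation).
#' The result is marked \code{partial}, i.e. pathway nodes are not required
#' to carry both regulator classes.
#'
#' @param path path to a SIF file.
#' @return an [Mdng-class].
#' @export
readSif <- function(path) {
  ln <- trimws(readLinesChecked(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(emptyMdng(partial = TRUE))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("SIF format error: expected 3 tab-separated columns at data line ",
         bad[1], call. = FALSE)
  src <- vapply(parts, `[[`, character(1), 1L)
  rel <- vapply(parts, `[[`, character(1), 2L)
  dst <- vapply(parts, `[[`, character(1), 3L)
  regClass <- ifelse(rel == "regulates", "miRNA", "drug")
  stripPrefix <- function(x) sub("^(pathway|miRNA|drug):", "", x)
  edges <- data.frame(regulator = stripPrefix(src), class = regClass,
                      pathway = stripPrefix(dst), stringsAsFactors = FALSE)
  mdngFromEdges(edges, partial = TRUE)
}

#' Write a result table as a commented TSV
#'
#' Writes a data.frame tab-delimited with a single \code{#}-prefixed header
#' line naming the columns, plus optional extra comment lines (run
#' metadata). Row order is preserved; no quoting.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param comments optional character vector of extra comment lines (written
#'   first, each prefixed with \code{"# "}).
#' @return the path, invisibly.
#' @export
writeTable <- function(table, path, comments = character()) {
  stopifnot(is.data.frame(table))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste0("# ", paste(names(table), collapse = "\t")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [writeTable()]
#'
#' The last comment line is taken as the column header.
#'
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
readTable <- function(path) {
  ln <- readLinesChecked(path)
  isComment <- startsWith(ln, "#")
  headerLine <- utils::tail(ln[isComment], 1)
  cols <- strsplit(sub("^#\\s*", "", headerLine), "\t", fixed = TRUE)[[1]]
  body <- ln[!isComment]
  if (!length(body)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  out <- utils::read.table(text = body, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  names(out) <- cols
  out
}
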