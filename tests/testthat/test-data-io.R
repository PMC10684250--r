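test_that("gene lists are case-normalised, deduplicated, order-preserving", {
  f <- tmpWrite(c("# comment", "tp53", "TP53", "", "BRCA1"))
  expect_identical(readGeneList(f), c("TP53", "BRCA1"))

  f100 <- tmpWrite(sprintf("gene%03d", 1:100))
  expect_length(readGeneList(f100), 100L)

  expect_error(readGeneList(tmpWrite(c("# only", "", "# comments"))),
               "no usable lines")
  expect_error(readGeneList(file.path(tempdir(), "no-such-file.txt")),
               "not found")
})

test_that("GMT parsing collapses within-row duplicates and rejects bad rows", {
  gsc <- readGmt(tmpWrite("P1\tdesc\tA\tB\tB", ".gmt"))
  expect_identical(unname(setSizes(gsc)), 2L)
  expect_identical(geneSet(gsc, "P1"), c("A", "B"))

  empty <- readGmt(tmpWrite(character(), ".gmt"))
  expect_s4_class(empty, "GeneSetCollection")
  expect_length(empty, 0L)

  two <- readGmt(tmpWrite(c(paste(c("P1", "d1", letters[1:5]), collapse = "\t"),
                            paste(c("P2", "d2", letters[6:12]), collapse = "\t")),
                          ".gmt"))
  expect_identical(unname(setSizes(two)), c(5L, 7L))

  expect_error(readGmt(tmpWrite(c("P1\td\tA", "P2\tdesc-only"), ".gmt")),
               "line 2")
  expect_error(readGmt(tmpWrite(c("P1\td\tA", "P1\td\tB"), ".gmt")),
               "duplicate set id")
})

test_that("GMT write/read round-trips the set structure", {
  gsc <- GeneSetCollection(list(P1 = c("A", "B"), P2 = LETTERS[3:9]),
                           descriptions = c("one", "two"))
  f <- tempfile(fileext = ".gmt")
  writeGmt(gsc, f)
  back <- readGmt(f)
  expect_identical(geneSets(back), geneSets(gsc))
  expect_identical(setDescriptions(back), setDescriptions(gsc))
})

test_that("target maps collapse duplicate pairs and report format errors", {
  tm <- suppressMessages(
    readTargetMap(tmpWrite(c("m1\tA", "m1\tA", "m1\tB")), "miRNA"))
  expect_identical(targetsOf(tm, "m1"), c("A", "B"))

  empty <- readTargetMap(tmpWrite(character()), "drug")
  expect_length(empty, 0L)

  expect_error(readTargetMap(tmpWrite(c("m1\tA", "m2\tA\tB")), "miRNA"),
               "line 2")
})

test_that("miRNA ids are lower-cased so database case conventions collapse", {
  tm <- suppressMessages(
    readTargetMap(tmpWrite(c("hsa-miR-155\tA", "hsa-mir-155\tB")), "miRNA"))
  expect_identical(regulators(tm), "hsa-mir-155")
  expect_setequal(targetsOf(tm, "hsa-mir-155"), c("A", "B"))
})

test_that("a large synthetic pair file keeps exact regulator and pair counts", {
  # 138 regulators sharing 12,101 distinct pairs, the scale of a curated
  # miRNA-target compilation
  set.seed(11)
  sizes <- rep(12101 %/% 138, 138)
  sizes[seq_len(12101 - sum(sizes))] <- sizes[seq_len(12101 - sum(sizes))] + 1
  pool <- sprintf("T%05d", 1:3000)
  lines <- unlist(lapply(seq_along(sizes), function(i)
    paste(sprintf("hsa-mir-%03d", i), sample(pool, sizes[i]), sep = "\t")))
  tm <- readTargetMap(tmpWrite(lines), "miRNA")
  expect_length(tm, 138L)
  expect_identical(sum(nTargets(tm)), 12101L)
})

test_that("restrictToUniverse intersects, flags emptied sets, is idempotent", {
  gsc <- GeneSetCollection(list(P1 = c("A", "B", "C"), P2 = c("X", "Y")))
  r <- suppressMessages(restrictToUniverse(gsc, c("A", "B")))
  expect_identical(geneSet(r, "P1"), c("A", "B"))
  expect_identical(geneSet(r, "P2"), character())
  expect_message(restrictToUniverse(gsc, c("A", "B")), "left empty")

  set.seed(42)
  for (i in 1:20) {
    members <- sample(LETTERS, sample(5:20, 1))
    uni <- sample(LETTERS, sample(5:20, 1))
    got <- suppressMessages(
      restrictToUniverse(GeneSetCollection(list(S = members)), uni))
    expect_setequal(geneSet(got, "S"), intersect(members, uni))
    again <- suppressMessages(restrictToUniverse(got, uni))
    expect_identical(geneSets(again), geneSets(got))
  }

  tm <- TargetMap(list(d1 = c("A", "Q")), "drug")
  rt <- suppressMessages(restrictToUniverse(tm, c("A", "B")))
  expect_identical(targetsOf(rt, "d1"), "A")
})

test_that("SIF export is deterministic and round-trips the edge set", {
  net <- Mdng(data.frame(regulator = c("m1", "d1"), class = c("miRNA", "drug"),
                         pathway = "P1"))
  f <- tempfile(fileext = ".sif")
  writeSif(net, f)
  ln <- readLines(f)
  expect_identical(ln[1], "# source\trelation\ttarget")
  expect_identical(sort(ln[-1]),
                   sort(c("miRNA:m1\tregulates\tpathway:P1",
                          "drug:d1\ttargets_pathway\tpathway:P1")))

  writeSif(emptyNet <- Mdng(data.frame(regulator = character(),
                                       class = character(),
                                       pathway = character())), f)
  expect_identical(readLines(f), "# source\trelation\ttarget")

  set.seed(7)
  edges <- unique(data.frame(
    regulator = sample(c(paste0("m", 1:8), paste0("d", 1:8)), 50, TRUE),
    pathway = sample(paste0("P", 1:6), 50, TRUE)))
  edges$class <- ifelse(startsWith(edges$regulator, "m"), "miRNA", "drug")
  net <- Mdng(edges, partial = TRUE)
  writeSif(net, f)
  back <- readSif(f)
  edgeKey <- function(x) {
    g <- mdngGraph(x)
    e <- igraph::ends(g, igraph::E(g))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(edgeKey(back), edgeKey(net))
})

test_that("readers are order-insensitive in the resulting structures", {
  rows <- c(paste(c("P1", "d", LETTERS[1:4]), collapse = "\t"),
            paste(c("P2", "d", LETTERS[5:7]), collapse = "\t"))
  a <- readGmt(tmpWrite(rows, ".gmt"))
  b <- readGmt(tmpWrite(rev(rows), ".gmt"))
  expect_identical(geneSets(a)[sort(setIds(a))], geneSets(b)[sort(setIds(b))])
})

test_that("commented TSV tables round-trip through writeTable/readTable", {
  df <- data.frame(id = c("a", "b"), x = c(1.5, -2), n = c(3L, 4L),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeTable(df, f, comments = "meta line")
  back <- readTable(f)
  expect_equal(back, df)
})
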