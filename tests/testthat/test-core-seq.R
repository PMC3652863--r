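# core_seq: I/O, GC content, annotation statistics, translation, protein MW

test_that("GenomeRecord validates inputs", {
    r <- GenomeRecord("ACGT", id = "x", topology = "circular")
    expect_s4_class(r, "GenomeRecord")
    expect_equal(length(r), 4L)
    expect_equal(topology(r), "circular")
    expect_error(GenomeRecord("ACGT", topology = "spiral"))
    expect_error(GenomeRecord("ACGT", features = data.frame(
        kind = "CDS", start = 2, end = 9, strand = "+")), "coordinates")
    expect_error(GenomeRecord("ACGT", features = data.frame(
        kind = "CDS", start = 1, end = 3, strand = "?")))
})

test_that("FASTA round trip preserves sequence and id", {
    fa <- tempfile(fileext = ".fasta")
    r <- GenomeRecord(random_dna(500), id = "t1")
    writeFasta(r, fa)
    back <- readSequences(fa)
    expect_length(back, 1L)
    expect_identical(as.character(genomeSeq(back[[1]])),
                     as.character(genomeSeq(r)))
    expect_identical(back[[1]]@id, "t1")
})

test_that("GenBank writer/reader round trip preserves everything used", {
    set.seed(11)
    feats <- data.frame(
        kind = c("CDS", "tRNA", "CDS"),
        start = c(10L, 200L, 480L), end = c(159L, 275L, 40L),
        strand = c("+", "-", "+"),
        label = c("g001", "t001", "g002"),
        product = c("hypothetical protein", "tRNA-Arg", "wrap protein"),
        wraps = c(FALSE, FALSE, TRUE))
    r <- GenomeRecord(random_dna(500), id = "gb1", topology = "circular",
                      features = feats)
    gb <- tempfile(fileext = ".gbk")
    writeGenBank(r, gb)
    back <- readSequences(gb, "genbank")[[1]]
    expect_identical(as.character(genomeSeq(back)),
                     as.character(genomeSeq(r)))
    expect_identical(topology(back), "circular")
    f2 <- featureTable(back)
    expect_identical(f2$kind, feats$kind)
    expect_identical(f2$start, feats$start)
    expect_identical(f2$end, feats$end)
    expect_identical(f2$strand, feats$strand)
    expect_identical(f2$label, feats$label)
    expect_identical(f2$product, feats$product)
    expect_identical(f2$wraps, feats$wraps)
})

test_that("GenBank parse errors name the offending line", {
    bad <- tempfile(fileext = ".gbk")
    writeLines(c("LOCUS       x 10 bp DNA linear",
                 "FEATURES             Location/Qualifiers",
                 "     CDS             join(1..2,4..5,7..8)",
                 "ORIGIN", "        1 acgtacgtac", "//"), bad)
    expect_error(readSequences(bad, "genbank"), "line 3")
    writeLines("just text", bad)
    expect_error(readSequences(bad, "genbank"), "LOCUS")
    expect_error(readSequences(tempfile(), "genbank"), "not found")
})

test_that("gcContent matches a hand count and ignores ambiguity codes", {
    expect_equal(gcContent("GGCC"), 1)
    expect_equal(gcContent("ATAT"), 0)
    expect_equal(gcContent("ACGT"), 0.5)
    expect_equal(gcContent("ACGTN"), 0.5)     # N excluded from denominator
    expect_error(gcContent(""), "empty")
    expect_error(gcContent("NNN"), "unambiguous")
    set.seed(5)
    s <- random_dna(10000)
    ch <- strsplit(s, "")[[1]]
    expect_equal(gcContent(s), mean(ch %in% c("G", "C")))
})

test_that("annotationStats counts union coding bases without double counting", {
    feats <- data.frame(
        kind = c("CDS", "CDS", "tRNA"),
        start = c(1L, 91L, 301L), end = c(100L, 190L, 376L),
        strand = "+", label = c("a", "b", "t"), product = "",
        wraps = FALSE)
    r <- GenomeRecord(random_dna(1000), features = feats)
    st <- annotationStats(r)
    expect_equal(st$n_genes, 3L)
    expect_equal(st$n_cds, 2L)
    expect_equal(st$n_trna, 1L)
    # union: 1..190 (overlap 91..100 counted once) + 301..376
    expect_equal(st$coding_bp, 190L + 76L)
    expect_equal(st$noncoding_pct, round(100 * (1 - 266 / 1000), 1))
    expect_equal(st$mean_cds_len, 100L)
})

test_that("annotationStats handles wrapping features on circles", {
    feats <- data.frame(kind = "CDS", start = 95L, end = 10L, strand = "+",
                        label = "w", product = "", wraps = TRUE)
    r <- GenomeRecord(random_dna(100), topology = "circular",
                      features = feats)
    st <- annotationStats(r)
    expect_equal(st$coding_bp, 16L)   # 95..100 plus 1..10
})

test_that("featureSeq resolves strand and wrapping", {
    r <- GenomeRecord("ATGAAACCCTAA", topology = "circular")
    plus <- data.frame(kind = "CDS", start = 1, end = 6, strand = "+",
                       label = "", product = "", wraps = FALSE)
    expect_equal(featureSeq(r, plus), "ATGAAA")
    minus <- plus; minus$strand <- "-"
    expect_equal(featureSeq(r, minus), oracle_revcomp("ATGAAA"))
    wrap <- data.frame(kind = "CDS", start = 10, end = 3, strand = "+",
                       label = "", product = "", wraps = TRUE)
    expect_equal(featureSeq(r, wrap), "TAAATG")
})

test_that("translateCds translates, strips the stop, and flags anomalies", {
    r <- GenomeRecord("ATGAAATAA", features = data.frame(
        kind = "CDS", start = 1, end = 9, strand = "+"))
    expect_equal(translateCds(r, featureTable(r)[1, ]), "MK")
    # minus strand
    s <- oracle_revcomp("ATGAAATAA")
    r2 <- GenomeRecord(s, features = data.frame(
        kind = "CDS", start = 1, end = 9, strand = "-"))
    expect_equal(translateCds(r2, featureTable(r2)[1, ]), "MK")
    # internal stop warns with the codon position
    r3 <- GenomeRecord("ATGTAAAAATAA", features = data.frame(
        kind = "CDS", start = 1, end = 12, strand = "+", label = "gX"))
    expect_warning(translateCds(r3, featureTable(r3)[1, ]), "codon 2")
    # non-triplet span errors
    r4 <- GenomeRecord("ATGAAAT", features = data.frame(
        kind = "CDS", start = 1, end = 7, strand = "+"))
    expect_error(translateCds(r4, featureTable(r4)[1, ]), "divisible by 3")
    expect_error(translateCds(r, data.frame(kind = "tRNA")), "not a CDS")
})

test_that("proteinMw matches frozen external oracle values", {
    # frozen values computed once with Biopython ProteinAnalysis (average
    # masses); tables differ from ours in the 3rd decimal per residue, so
    # compare at 0.1 Da
    expect_equal(proteinMw("GG", kDa = FALSE), 132.1179, tolerance = 0.1 / 132)
    expect_equal(proteinMw("MKWVTFISLLFLFSSAYS", kDa = FALSE), 2140.5405,
                 tolerance = 0.1 / 2140)
    expect_equal(proteinMw("ACDEFGHIKLMNPQRSTVWY", kDa = FALSE), 2395.7134,
                 tolerance = 0.1 / 2395)
    expect_equal(proteinMw("GG"), 0.13)                   # kDa, 2 decimals
    expect_lt(proteinMw("G", monoisotopic = TRUE, kDa = FALSE),
              proteinMw("G", kDa = FALSE))
    expect_error(proteinMw("GXG"), "unknown amino acid")
})

test_that("protein MW is additive in residues (internal consistency)", {
    set.seed(42)
    p1 <- random_protein(30); p2 <- random_protein(20)
    water <- proteinMw("", kDa = FALSE)
    expect_equal(proteinMw(paste0(p1, p2), kDa = FALSE),
                 proteinMw(p1, kDa = FALSE) + proteinMw(p2, kDa = FALSE) -
                     water)
})
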