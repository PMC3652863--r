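# restriction: site scanning, digest simulation, fragment chemistry

test_that("findSites locates palindromic sites with correct cut offsets", {
    rec <- GenomeRecord("TTGGCGCCTT")
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    sites <- findSites(rec, narI)
    expect_equal(sites$position, 3L)
    # GG^CGCC: top cut after position 3+2-1 = 4, bottom after 3+4-1 = 6
    expect_equal(sites$cut_top_after, 4L)
    expect_equal(sites$cut_bottom_after, 6L)
})

test_that("non-palindromic recognitions are found on both strands", {
    enz <- data.frame(name = "AsyI", recognition = "GACGTG",
                      cut_top = 1L, cut_bottom = 5L)
    # plant the site forward at 3 and reverse-complement (CACGTC) at 15
    rec <- GenomeRecord(paste0("TT", "GACGTG", "TTTTTTT", "CACGTC", "TT"))
    sites <- findSites(rec, enz)
    expect_equal(sites$position, c(3L, 16L))
    expect_equal(sites$strand, c("+", "-"))
    # minus-strand site: cut_top_after = pos + m - cut_bottom - 1
    expect_equal(sites$cut_top_after[2], 16L + 6L - 5L - 1L)
    expect_equal(sites$cut_bottom_after[2], 16L + 6L - 1L - 1L)
})

test_that("degenerate IUPAC recognitions match only real bases", {
    enz <- data.frame(name = "DegI", recognition = "GRCGYC",
                      cut_top = 2L, cut_bottom = 4L)
    rec <- GenomeRecord("TTGACGCCTTGGCGTCTT")    # GACGCC at 3, GGCGTC at 11
    sites <- findSites(rec, enz)
    expect_setequal(sites$position, c(3L, 11L))
    # an N in the genome must never satisfy the pattern
    recN <- GenomeRecord("TTGNCGCCTT")
    expect_equal(nrow(findSites(recN, enz)), 0L)
})

test_that("circular topology finds origin-spanning sites", {
    s <- paste0("CGCCTTTTTTTTTTGG")                # GGCGCC wraps 15..4
    rec <- GenomeRecord(s, topology = "circular")
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    expect_equal(findSites(rec, narI)$position, 15L)
    expect_equal(nrow(findSites(GenomeRecord(s), narI)), 0L)   # linear: none
})

test_that("singleCutters reports exactly-once enzymes alphabetically", {
    s <- paste0(strrep("AT", 20), "GGCGCC", strrep("TA", 20),
                "TGCGCA", strrep("AT", 10), "TGCGCA")
    rec <- GenomeRecord(s)
    sc <- singleCutters(rec)                      # NarI once, FspI twice
    expect_equal(sc$name, "NarI")
    s2 <- paste0(s, "GCGGCCGC")
    sc2 <- singleCutters(GenomeRecord(s2))
    expect_equal(sc2$name, c("NarI", "NotI"))     # alphabetical
})

test_that("linear digest fragments tile the molecule with sticky ends", {
    left <- strrep("T", 30); right <- strrep("A", 30)
    s <- paste0(left, "GGCGCC", right)
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    frags <- digest(GenomeRecord(s), narI)
    expect_length(frags, 2L)
    tab <- fragmentTable(frags)
    # GG^CGCC leaves a 2 nt 5' overhang CG on each new end
    expect_equal(tab$right_overhang[1], "CG")
    expect_equal(tab$right_polarity[1], "5'")
    expect_equal(tab$left_overhang[2], "CG")
    expect_equal(tab$left_polarity[2], "5'")
    expect_equal(tab$left_polarity[1], "none")
    expect_equal(tab$right_polarity[2], "none")
    # top strands rejoin to the original sequence
    expect_equal(tab$length[1] + tab$length[2], nchar(s) + 2L)  # overhang dup
})

test_that("blunt cutters produce no overhangs", {
    s <- paste0(strrep("A", 20), "TGCGCA", strrep("T", 20))
    fspI <- builtinEnzymes()[builtinEnzymes()$name == "FspI", ]
    tab <- fragmentTable(digest(GenomeRecord(s), fspI))
    expect_true(all(tab$left_overhang == "" & tab$right_overhang == ""))
    expect_equal(sum(tab$length), nchar(s))
    expect_equal(tab$length, c(23L, 23L))
})

test_that("circular digest linearizes at the first cut and conserves bases", {
    set.seed(21)
    body <- random_dna(200)
    body <- gsub("GGCGCC|GCGGCCGC|TGCGCA", "AAAAAA", body)
    s <- paste0(body, "GGCGCC", random_dna(0), "TGCGCA")
    s <- paste0(substr(s, 1, 150), "GCGGCCGC", substr(s, 151, nchar(s)))
    rec <- GenomeRecord(s, topology = "circular")
    enz <- builtinEnzymes()
    nCuts <- sum(vapply(seq_len(nrow(enz)), function(i)
        nrow(findSites(rec, enz[i, ])), 1L))
    frags <- digest(rec, enz)
    expect_length(frags, nCuts)
    # total top-strand bases across fragments equal the genome length
    tops <- vapply(frags, function(f) f@topEnd - f@topStart + 1L, 1L)
    expect_equal(sum(tops), nchar(s))
})

test_that("a circular molecule with no sites returns intact", {
    rec <- GenomeRecord(strrep("AT", 50), topology = "circular")
    frags <- digest(rec, builtinEnzymes())
    expect_length(frags, 1L)
    expect_equal(fragmentLength(frags[[1]]), 100L)
})

test_that("digesting a dtr physical molecule releases terminal fragments", {
    g <- generateGenome(syntheticGenomeSpec(length = 30000L, L = 500L,
        nCds = 40L, nTrna = 4L,
        plantedSites = data.frame(recognition = c("GGCGCC", "GCGGCCGC"),
                                  position = c(2500L, 27000L)),
        seed = 3L))
    mol <- g$molecule
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    tab <- fragmentTable(digest(mol, narI))
    expect_equal(nrow(tab), 2L)   # single cut releases the left terminal band
    # the genome-end fragments are blunt on their outer side
    expect_equal(tab$left_polarity[1], "none")
    expect_equal(tab$right_polarity[nrow(tab)], "none")
    # left terminal fragment: bottom strand runs to the bottom cut at site+3
    site <- g$truth$site_positions[1]
    expect_equal(tab$length[1], site + 3L)
    # fragment lengths cover the physical molecule (minus the shared 2 nt
    # overhang counted on both fragments)
    expect_equal(sum(tab$length), length(mol) + 2L)
})

test_that("cohesive termini are not cut within single-stranded regions", {
    # put a NarI site inside the 3' overhang region: unreachable by the enzyme
    set.seed(9)
    core <- gsub("GGCGCC", "ATATAT", random_dna(300))
    u <- paste0("GGGCGCCG", core)        # overhang contains GGCGCC
    mol <- PhysicalMolecule(u, "cos_3", 8L)
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    frags <- digest(mol, narI)
    expect_length(frags, 1L)
})

test_that("s1Trim removes single-stranded extensions from fragments", {
    left <- strrep("T", 30); right <- strrep("A", 30)
    s <- paste0(left, "GGCGCC", right)
    narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
    frags <- digest(GenomeRecord(s), narI)
    trimmed <- s1Trim(frags[[1]])
    expect_equal(leftOverhang(trimmed)$polarity, "none")
    expect_equal(rightOverhang(trimmed)$polarity, "none")
    expect_equal(fragmentLength(trimmed), fragmentLength(frags[[1]]) - 2L)
})

test_that("readEnzymes validates its input", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("name\trecognition\tcut_top\tcut_bottom",
                 "TestI\tgaattc\t1\t5"), tsv)
    db <- readEnzymes(tsv)
    expect_equal(db$recognition, "GAATTC")
    writeLines(c("name\trecognition\tcut_top\tcut_bottom",
                 "BadI\tGAATTC\t9\t5"), tsv)
    expect_error(readEnzymes(tsv), "within-site")
    writeLines("name\tsite", tsv)
    expect_error(readEnzymes(tsv), "columns")
})

test_that("the shipped enzyme TSV loads and is consistent with built-ins", {
    path <- system.file("extdata", "enzymes.tsv", package = "phageTermini")
    db <- readEnzymes(path)
    expect_true(all(c("NarI", "NotI", "FspI") %in% db$name))
    merged <- merge(db, builtinEnzymes(), by = "name")
    expect_equal(merged$recognition.x, merged$recognition.y)
})
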