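# termini: run-off simulation, classification, physical reconstruction, S1

test_that("PhysicalMolecule validity enforces the dtr invariant", {
    expect_error(PhysicalMolecule("ACGTACGTAA", "dtr", 2L), "repeat")
    m <- PhysicalMolecule("ACGTACGTAC", "dtr", 2L)   # prefix AC == suffix AC
    expect_equal(repeatLength(m), 2L)
    expect_error(PhysicalMolecule("ACGT", "blunt", 1L))
})

test_that("simulateRunoff reproduces the strand geometry by hand", {
    # blunt 20-mer: + read from primer 11 runs to the right end
    u <- "ACGTTGCAACGGATCCTTGA"
    mol <- PhysicalMolecule(u, "blunt", 0L)
    plus <- simulateRunoff(mol, 11, "+")
    expect_equal(as.character(plus@sequence), substr(u, 11, 20))
    expect_equal(plus@side, "right_end")
    minus <- simulateRunoff(mol, 8, "-")
    expect_equal(as.character(minus@sequence), oracle_revcomp(substr(u, 1, 8)))
    expect_equal(minus@side, "left_end")
    expect_error(simulateRunoff(mol, 25, "+"), "anneal")
})

test_that("runoff reads extend into overhangs/repeats as chemistry dictates", {
    core <- "ACGGATCCTTGACCAGTAAC"
    # cos_5: bottom strand extends L = 4 past the top strand on the right
    u5 <- paste0(core, substr(core, 1, 4))
    m5 <- PhysicalMolecule(u5, "cos_5", 4L)
    plus <- simulateRunoff(m5, 15, "+")
    # template is the bottom strand: read runs to the bottom 5' end (u end)
    expect_equal(as.character(plus@sequence), substr(u5, 15, 24))
    minus <- simulateRunoff(m5, 6, "-")
    expect_equal(as.character(minus@sequence), oracle_revcomp(substr(u5, 1, 6)))
    # cos_3: top strand extends L past the bottom on the right
    u3 <- paste0(substr(core, 17, 20), core)
    m3 <- PhysicalMolecule(u3, "cos_3", 4L)
    plus3 <- simulateRunoff(m3, 15, "+")
    # + read stops where the bottom strand (template) ends: core position 16
    expect_equal(as.character(plus3@sequence), substr(core, 15, 16))
    # - read reaches the top strand's 5' end, which is recessed by L
    minus3 <- simulateRunoff(m3, 6, "-")
    expect_equal(as.character(minus3@sequence),
                 oracle_revcomp(substr(core, 1, 6)))
})

test_that("classification recovers all architectures exactly (sweep)", {
    # criterion: all four architectures, cos L sampled across 1..99,
    # dtr L in {100, 101, 500, 1190, 5000}, 20 seeds each, 100% exact
    cosL <- c(1L, 2L, 3L, 4L, 7L, 12L, 19L, 34L, 61L, 99L)
    cases <- rbind(
        data.frame(arch = "blunt", L = 0L),
        data.frame(arch = "cos_3", L = cosL),
        data.frame(arch = "cos_5", L = cosL),
        data.frame(arch = "dtr", L = c(100L, 101L, 500L, 1190L, 5000L)))
    fails <- character(0)
    for (i in seq_len(nrow(cases))) {
        for (seed in 1:20) {
            g <- generateGenome(syntheticGenomeSpec(
                length = 12000L, architecture = cases$arch[i],
                L = cases$L[i], nCds = 18L, nTrna = 2L,
                plantedSites = NULL, seed = seed))
            reads <- simulateTerminalReads(g$molecule, anchor = 400L)
            call <- classifyTermini(g$assembly, reads$right, reads$left)
            if (call@category != cases$arch[i] || call@L != cases$L[i] ||
                !identical(call@repeatSeq, g$truth$repeat_seq))
                fails <- c(fails, paste(cases$arch[i], cases$L[i], seed))
        }
    }
    expect_identical(fails, character(0))
})

test_that("the 100 bp threshold separates cos_5 from dtr at the boundary", {
    for (L in c(99L, 100L, 101L)) {
        arch <- if (L >= 100L) "dtr" else "cos_5"
        g <- generateGenome(syntheticGenomeSpec(length = 12000L,
            architecture = arch, L = L, nCds = 18L, nTrna = 2L,
            plantedSites = NULL, seed = 5L))
        reads <- simulateTerminalReads(g$molecule, anchor = 400L)
        call <- classifyTermini(g$assembly, reads$right, reads$left)
        expect_equal(call@category, arch)
        expect_equal(call@L, L)
    }
})

test_that("classification tolerates read errors when a rate is allowed", {
    g <- generateGenome(syntheticGenomeSpec(length = 12000L,
        architecture = "dtr", L = 300L, nCds = 18L, nTrna = 2L,
        plantedSites = NULL, seed = 8L))
    reads <- simulateTerminalReads(g$molecule, anchor = 400L)
    mutate_tail <- function(r) {
        s <- as.character(r@sequence)
        # flip one base 50 nt from the read start (seed region untouched)
        at <- 50L
        base <- substr(s, at, at)
        substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), base)[1]
        new("TerminalRead", sequence = Biostrings::DNAString(s),
            side = r@side, primerPos = r@primerPos, errorFree = FALSE)
    }
    rr <- mutate_tail(reads$right)
    expect_error(classifyTermini(g$assembly, rr, reads$left), "map")
    call <- classifyTermini(g$assembly, rr, reads$left,
                            maxMismatchRate = 0.01)
    expect_equal(call@category, "dtr")
    expect_equal(call@L, 300L)
})

test_that("ambiguous reads raise an informative error", {
    s <- paste0(strrep("ACGT", 100), strrep("ACGT", 100))
    rec <- GenomeRecord(s, topology = "circular")
    expect_error(classifyTermini(rec, strrep("ACGT", 10),
                                 oracle_revcomp(strrep("ACGT", 10))),
                 "multiple")
    set.seed(2)
    rec2 <- GenomeRecord(random_dna(500), topology = "circular")
    expect_error(classifyTermini(rec2, random_dna(60), random_dna(60)),
                 "does not map")
    expect_error(classifyTermini(GenomeRecord(random_dna(500)),
                                 "ACGTACGT", "ACGTACGT"), "circular")
})

test_that("reconstructPhysical inverts the simulation for every architecture", {
    for (arch in c("blunt", "cos_3", "cos_5", "dtr")) {
        L <- switch(arch, blunt = 0L, cos_3 = 9L, cos_5 = 15L, dtr = 250L)
        g <- generateGenome(syntheticGenomeSpec(length = 12000L,
            architecture = arch, L = L, nCds = 18L, nTrna = 2L,
            plantedSites = NULL, seed = 12L))
        reads <- simulateTerminalReads(g$molecule, anchor = 400L)
        call <- classifyTermini(g$assembly, reads$right, reads$left)
        mol2 <- reconstructPhysical(g$assembly, call)
        expect_identical(as.character(mol2@unionSeq),
                         as.character(g$molecule@unionSeq))
        expect_identical(architecture(mol2), arch)
    }
    # inconsistent calls are rejected
    g <- generateGenome(syntheticGenomeSpec(length = 12000L,
        architecture = "dtr", L = 150L, nCds = 18L, nTrna = 2L,
        plantedSites = NULL, seed = 12L))
    bad <- new("TerminusCall", category = "dtr", L = 150L,
               repeatSeq = strrep("A", 150L), a = 1L, b = 150L, notes = "")
    expect_error(reconstructPhysical(g$assembly, bad), "inconsistent")
})

test_that("s1Trim converts cohesive molecules to blunt duplex cores", {
    core <- "ACGGATCCTTGACCAGTAAC"
    # S1 digests the single-stranded overhangs, leaving the N - L duplex core
    m5 <- PhysicalMolecule(paste0(core, substr(core, 1, 4)), "cos_5", 4L)
    t5 <- s1Trim(m5)
    expect_equal(architecture(t5), "blunt")
    expect_equal(topStrand(t5), substr(core, 5, 20))
    m3 <- PhysicalMolecule(paste0(substr(core, 17, 20), core), "cos_3", 4L)
    t3 <- s1Trim(m3)
    expect_equal(architecture(t3), "blunt")
    expect_equal(topStrand(t3), substr(core, 1, 16))
    # dtr and blunt molecules are S1-resistant: untouched (the paper's
    # evidence that the 1190 bp repeat is double-stranded)
    mD <- PhysicalMolecule(paste0(core, substr(core, 1, 4)), "dtr", 4L)
    expect_identical(s1Trim(mD), mD)
    mB <- PhysicalMolecule(core, "blunt", 0L)
    expect_identical(s1Trim(mB), mB)
})

test_that("terminusCallAsList exposes the call fields", {
    call <- new("TerminusCall", category = "cos_5", L = 12L,
                repeatSeq = strrep("A", 12), a = 5L, b = 16L, notes = "")
    lst <- terminusCallAsList(call)
    expect_equal(lst$category, "cos_5")
    expect_equal(lst$L, 12L)
    expect_equal(lst$a, 5L)
})
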