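# Case-report assembly and rendering.

# A duplication_call as the caller would emit for pair/dup, without rerunning
# the signal machinery.
stub_call <- function(pair, dup, total = 3L, defer = character(0),
                      sample_id = "S1") {
  votes <- if (identical(dup, "DEFER")) data.frame() else
    data.frame(assay_id = c("c.886C>T", "c.1457G>C"), z = c(8.1, -7.9),
               direction = c("toward_var", "toward_ref"),
               confident = TRUE, discordant = FALSE,
               comparator_count = 5L, directional = TRUE, vote = dup,
               stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, result = dup, pair = pair,
                 votes = votes, defer_reasons = defer, total_copies = total),
            class = "duplication_call")
}

test_that("three full copies report the duplicated haplotype as ×2", {
  r <- resolve(stub_call(c("*1", "*41"), "*1"), defs_pkg,
               structures = enumerate_structures(3, 3, 3)[1, , drop = FALSE])
  expect_identical(r$status, "reported")
  expect_identical(r$diplotype, "*1×2/*41")
  expect_equal(r$activity_score$value, 2.5)
  expect_identical(r$phenotype, "Ultrarapid")
})

test_that("a deferred call becomes reflex sequencing with its reasons", {
  r <- resolve(stub_call(c("*1", "*41"), "DEFER", defer = "conflicting_votes"),
               defs_pkg)
  expect_identical(r$status, "reflex_sequencing")
  expect_true("conflicting_votes" %in% r$defer_reasons)
})

test_that("hybrid structures attach in tandem to the partner haplotype", {
  s <- consistency_check(enumerate_structures(4, 3, 3), n_full_expected = 3)
  r <- resolve(stub_call(c("*4", "*41"), "*41"), defs_pkg, structures = s)
  expect_identical(r$diplotype, "*68+*4/*41×2")
  expect_equal(r$activity_score$value, 1)
  r <- resolve(stub_call(c("*1", "*4"), "*1"), defs_pkg, structures = s)
  expect_identical(r$diplotype, "*1×2/*68+*4")
  s13 <- consistency_check(enumerate_structures(3, 4, 4), n_full_expected = 3)
  r <- resolve(stub_call(c("*2A", "*9"), "*2A"), defs_pkg, structures = s13)
  expect_identical(r$diplotype, "*13+*2A×2/*9")
  expect_equal(r$activity_score$value, 2.5)
})

test_that("an unphaseable extra copy is reported as equal-score alternatives", {
  s <- consistency_check(enumerate_structures(4, 4, 4), n_full_expected = 4)
  r <- resolve(stub_call(c("*2A", "*17"), "*2A", total = 4L), defs_pkg,
               structures = s, extra_allele = "*2")
  expect_identical(r$status, "reported")
  expect_identical(r$diplotype, "*2A×2/*2+*17")
  expect_identical(r$alternatives, "*2A×2+*2/*17")
  expect_equal(r$activity_score$value, 3.5)
  expect_identical(r$phenotype, "Ultrarapid")
  # both arrangements carry the same copies, so the scores must agree
  expect_equal(activity_score(r$diplotype)$value,
               activity_score(r$alternatives)$value)
})

test_that("a duplicated allele absent from the genotype is contradictory", {
  expect_error(resolve(stub_call(c("*1", "*41"), "*9"), defs_pkg),
               "absent from the genotype pair")
})

test_that("reports render to lossless JSON and readable text", {
  r <- resolve(stub_call(c("*1", "*41"), "*1"), defs_pkg)
  json <- render_report(r, "json")
  back <- parse_report(json)
  expect_identical(back$status, "reported")
  expect_identical(back$diplotype, "*1×2/*41")
  expect_identical(back$activity_score, "2.5")
  expect_equal(back$evidence$votes$z, r$evidence$votes$z)
  # render -> parse -> render is a fixed point
  expect_identical(jsonlite::fromJSON(json, simplifyVector = FALSE),
                   jsonlite::fromJSON(render_report(r, "json"),
                                      simplifyVector = FALSE))

  rr <- resolve(stub_call(c("*1", "*41"), "DEFER", total = NA_integer_,
                          defer = c("weak_shift", "replicate_discordance")),
                defs_pkg)
  txt <- render_report(rr, "text")
  for (reason in rr$defer_reasons) {
    expect_equal(lengths(regmatches(txt, gregexpr(reason, txt, fixed = TRUE))),
                 1L, info = reason)
  }
  expect_error(render_report(r, "xml"), "unknown report format")
})
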