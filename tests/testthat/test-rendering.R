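# Rendering is checked by parsing the SVG output (the canonical vector
# backend) with xml2: marker groups, domain boxes and track bands carry
# stable class/data attributes.

ret_spec <- function(...) {
  fx <- make_ret_like_fixture()
  plot_spec(fx$context, fx$mutations, mutations2 = fx$mutations_secondary,
            domains = fx$domains, ptms = fx$ptms,
            track_labels = c(primary = "All", secondary = "MEN2A"), ...)
}

test_that("layout places every enabled track exactly once, in disjoint bands", {
  spec <- ret_spec()
  lay <- layout_tracks(spec)
  expect_equal(lay$track, c("title", "mutations_secondary",
                            "mutations_primary", "backbone", "ptm", "axis"))
  expect_true(all(lay$y0 < lay$y1))
  expect_equal(lay$y0[-1], lay$y1[-nrow(lay)])  # disjoint and contiguous

  ctx <- protein_context(100, "mini")
  minimal <- plot_spec(ctx, mutation_df(5L))
  expect_equal(layout_tracks(minimal)$track,
               c("title", "mutations_primary", "backbone", "axis"))
})

test_that("residue-to-x mapping is affine, monotone and inside the drawable span", {
  spec <- zoom_view(ret_spec(), 600, 700)
  lay <- layout_tracks(spec)
  x <- function(p) attr(lay, "x_a") * p + attr(lay, "x_b")
  expect_lt(x(636), x(653))
  expect_true(x(636) > 0 && x(653) < attr(lay, "width"))
  # affine: equal residue steps give equal pixel steps
  expect_equal(x(650) - x(640), x(660) - x(650))
  # monotone across the window
  ps <- 600:700
  expect_true(all(diff(x(ps)) > 0))
})

test_that("a full RET-like figure contains all tracks, domains and markers", {
  f <- tempfile(fileext = ".svg")
  spec <- ret_spec()
  render(spec, f)
  expect_equal(count_svg_nodes(f, "//g[@class='domain']"), 4L)
  expect_equal(count_svg_nodes(f, "//g[starts-with(@class,'track ')]"), 2L)
  expect_equal(count_svg_nodes(f, "//g[@class='marker marker-mutations_primary']"),
               nrow(spec$mutations))
  expect_equal(count_svg_nodes(f, "//g[@class='marker marker-mutations_secondary']"),
               nrow(spec$mutations2))
  doc <- xml2::read_xml(f); xml2::xml_ns_strip(doc)
  names <- xml2::xml_attr(xml2::xml_find_all(doc, "//g[@class='domain']"),
                          "data-name")
  expect_equal(names, c("Signal Peptide", "Cadherin", "Transmembrane",
                        "Tyrosine Kinase"))
})

test_that("zooming drops exactly the out-of-window markers and clips straddling domains", {
  spec <- ret_spec()
  zoomed <- zoom_view(spec, 600, 750)
  expect_null(spec$zoom)  # input not mutated
  f <- tempfile(fileext = ".svg")
  render(zoomed, f)
  in_win <- sum(spec$mutations$position >= 600 & spec$mutations$position <= 750)
  expect_equal(count_svg_nodes(f, "//g[@class='marker marker-mutations_primary']"),
               in_win)
  expect_equal(count_svg_nodes(f, "//g[@class='marker marker-mutations_secondary']"),
               6L)  # the whole cluster lies inside the window
  # Tyrosine Kinase (724..1005) straddles the right edge: partially drawn
  doc <- xml2::read_xml(f); xml2::xml_ns_strip(doc)
  names <- xml2::xml_attr(xml2::xml_find_all(doc, "//g[@class='domain']"),
                          "data-name")
  expect_true("Tyrosine Kinase" %in% names)
  expect_false("Signal Peptide" %in% names)  # fully outside
})

test_that("identity zoom renders byte-identically to the unzoomed spec", {
  spec <- ret_spec()
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  render(spec, f1)
  render(zoom_view(spec, 1, spec$context$length), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid zoom windows are rejected", {
  spec <- ret_spec()
  expect_error(zoom_view(spec, 700, 600), "inverted")
  expect_error(zoom_view(spec, 0, 10), "outside")
  expect_error(zoom_view(spec, 1, 9999), "outside")
})

test_that("mutations at one position stack into distinct heads", {
  ctx <- protein_context(100, "stack")
  muts <- mutation_df(c(50L, 50L, 50L, 20L), ref = "C",
                      alt = c("R", "S", "W", "R"))
  f <- tempfile(fileext = ".svg")
  render(plot_spec(ctx, muts), f)
  doc <- xml2::read_xml(f); xml2::xml_ns_strip(doc)
  heads <- xml2::xml_find_all(doc,
    "//g[@class='marker marker-mutations_primary']/circle")
  expect_equal(length(heads), 4L)
  at50 <- xml2::xml_find_all(doc,
    "//g[@data-position='50']/circle")
  expect_equal(length(at50), 3L)
  expect_equal(length(unique(xml2::xml_attr(at50, "cy"))), 3L)
  expect_equal(length(unique(xml2::xml_attr(at50, "cx"))), 1L)
})

test_that("marker labels follow <ref><position><alt>", {
  ctx <- protein_context(1000, "labels")
  f <- tempfile(fileext = ".svg")
  render(plot_spec(ctx, mutation_df(634L, "C", "R")), f)
  doc <- xml2::read_xml(f); xml2::xml_ns_strip(doc)
  m <- xml2::xml_find_first(doc, "//g[@data-position='634']")
  expect_equal(xml2::xml_attr(m, "data-label"), "C634R")
  expect_equal(xml2::xml_text(xml2::xml_find_first(m, "./text")), "C634R")
})

test_that("conservation, reference and score tracks appear when enabled", {
  ctx <- protein_context(60, "cons")
  cfg <- fixture_config(protein_length = 60, n_alignment_sequences = 5,
                        seed = 5)
  prof <- conservation_scores(simulate_alignment(cfg), context = ctx)
  spec <- plot_spec(ctx, mutation_df(30L), profile = prof, show_score = TRUE,
                    show_reference_sequence = TRUE)
  f <- tempfile(fileext = ".svg")
  render(spec, f)
  expect_equal(count_svg_nodes(f, "//g[@class='conservation']"), 1L)
  expect_equal(count_svg_nodes(f, "//g[@class='reference_sequence']"), 1L)
  expect_equal(count_svg_nodes(f, "//g[@class='score']"), 1L)
  # 60-residue window: letters, one per position
  expect_equal(count_svg_nodes(f, "//g[@class='conservation']/text"), 60L)
  expect_equal(count_svg_nodes(f, "//g[@class='reference_sequence']/text"), 60L)
})

test_that("the reference-sequence track is suppressed on wide windows", {
  ctx <- protein_context(500, "wide")
  cfg <- fixture_config(protein_length = 500, n_alignment_sequences = 3,
                        seed = 6)
  prof <- conservation_scores(simulate_alignment(cfg), context = ctx)
  spec <- plot_spec(ctx, mutation_df(30L), profile = prof,
                    show_reference_sequence = TRUE)
  f <- tempfile(fileext = ".svg")
  expect_message(render(spec, f), "suppressed")
  expect_equal(count_svg_nodes(f, "//g[@class='reference_sequence']"), 0L)
  # but zooming below the legibility limit brings it back
  expect_no_message(render(zoom_view(spec, 101, 300), f))
  expect_equal(count_svg_nodes(f, "//g[@class='reference_sequence']"), 1L)
})

test_that("flags require the inputs they draw from", {
  ctx <- protein_context(100, "x")
  expect_error(plot_spec(ctx, mutation_df(5L), show_score = TRUE), "profile")
  expect_error(plot_spec(ctx, mutation_df(5L),
                         show_reference_sequence = TRUE), "profile")
})

test_that("PDF and PNG backends write non-empty files", {
  spec <- ret_spec()
  fpdf <- tempfile(fileext = ".pdf")
  render(spec, fpdf)
  expect_gt(file.size(fpdf), 1000)
  fpng <- tempfile(fileext = ".png")
  render(spec, fpng)
  expect_gt(file.size(fpng), 1000)
  expect_error(render(spec, tempfile(fileext = ".gif")), "unsupported")
})

test_that("config files override rendering settings and reject unknown keys", {
  f <- write_tmp(c("# colors", "color_primary = #000000",
                   "domain_palette = red, blue", "dpi = 72",
                   "labels = false"), ext = ".cfg")
  cfg <- read_render_config(f)
  expect_equal(cfg$color_primary, "#000000")
  expect_equal(cfg$domain_palette, c("red", "blue"))
  expect_equal(cfg$dpi, 72)
  expect_false(cfg$labels)
  expect_equal(cfg$color_secondary, render_config()$color_secondary)
  expect_error(read_render_config(write_tmp("nope = 1", ext = ".cfg")),
               "unknown config key")
  # labels = false removes label text from markers
  out <- tempfile(fileext = ".svg")
  render(plot_spec(protein_context(100, "x"), mutation_df(5L)), out,
         config = cfg)
  expect_equal(count_svg_nodes(out, "//g[starts-with(@class,'marker')]/text"),
               0L)
})
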