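# Topography collection and the reflexive-part lattice.

test_that("topography collection unions fillers with their ancestors", {
  m <- get_model()
  expect_true(all(c("NCIT:A_CEC", "NCIT:A_COL", "NCIT:A_CRR", "NCIT:A_INT",
                    "NCIT:A_GIS", "NCIT:A_LI", "NCIT:C12971", "NCIT:A_LOQ")
                  %in% m$topos))
  # cell parts never asserted as fillers stay out
  expect_false("NCIT:A_BG" %in% m$topos)

  # single filler expands to its full ancestor chain
  onto <- demo_ontology()
  neo <- extract_neoplasm_graph(onto)
  neo$sites <- tibble::tibble(concept = "NCIT:C9329", site = "NCIT:A_CEC")
  topos <- collect_topographies(neo, m$index)
  expect_setequal(topos, c("NCIT:A_CEC", "NCIT:A_LI", "NCIT:A_INT", "NCIT:A_GIS"))

  # without ancestor completion only the asserted fillers remain
  expect_setequal(collect_topographies(neo, m$index, ancestor_completion = FALSE),
                  "NCIT:A_CEC")

  neo$sites <- neo$sites[0, ]
  expect_length(collect_topographies(neo, m$index), 0)
})

test_that("reflexive-part lattice mirrors the anatomy order on the collected set", {
  m <- get_model()
  rp <- m$rp
  expect_equal(nrow(rp$classes), length(m$topos))
  # quadrant below breast is a direct (Hasse) edge
  expect_true(any(rp$edges$from == "RP:NCIT:A_LOQ" &
                    rp$edges$to == "RP:NCIT:C12971"))
  # closure of the Hasse edges equals the anatomy order restricted to topos
  clo <- naive_closure(rp$classes$id, rp$edges)
  for (s in m$topos) {
    for (t in m$topos) {
      expect_equal(unname(clo[paste0("RP:", s), paste0("RP:", t)]),
                   anat_reachable(m$index, s, t),
                   info = paste(s, t))
    }
  }
})

test_that("singleton topography set yields one node and no edges", {
  m <- get_model()
  rp <- build_rp_lattice("NCIT:C12971", m$index)
  expect_equal(nrow(rp$classes), 1)
  expect_equal(nrow(rp$edges), 0)
})

test_that("random partonomies reproduce oracle reachability", {
  for (s in 1:3) {
    onto <- random_ontology(n_anatomy = 30, n_neoplasm = 5, n_morph = 3, seed = s)
    orc <- brute_force_oracle(onto)
    index <- extract_anatomy_graph(onto)
    topos <- orc$topos
    if (length(topos) < 2) next
    rp <- build_rp_lattice(topos, index)
    clo <- naive_closure(rp$classes$id, rp$edges)
    for (a in topos) {
      expect_setequal(sub("^RP:", "", colnames(clo)[clo[paste0("RP:", a), ]]),
                      intersect(colnames(orc$anat_leq)[orc$anat_leq[a, ]], topos))
    }
  }
})

test_that("adding a part edge never removes an RP subsumption", {
  onto <- demo_ontology()
  index1 <- extract_anatomy_graph(onto)
  neo <- extract_neoplasm_graph(onto)
  topos <- collect_topographies(neo, index1)
  rp1 <- build_rp_lattice(topos, index1)
  clo1 <- naive_closure(rp1$classes$id, rp1$edges)
  # link colon into the colorectal region (the repair the audit suggests)
  onto2 <- ontology(onto$concepts, is_a = onto$is_a,
                    parts = dplyr::bind_rows(
                      onto$parts,
                      tibble::tibble(child = "NCIT:A_COL", parent = "NCIT:A_CRR",
                                     role = "PART_PHYSICAL")),
                    sites = onto$sites, morphs = onto$morphs)
  index2 <- extract_anatomy_graph(onto2)
  rp2 <- build_rp_lattice(collect_topographies(neo, index2), index2)
  clo2 <- naive_closure(rp2$classes$id, rp2$edges)
  common <- intersect(rownames(clo1), rownames(clo2))
  expect_true(all(clo2[common, common][clo1[common, common]]))
})
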