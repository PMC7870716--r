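test_that("arbor table encodes the published projection patterns", {
  arb <- cx_arbors()
  cls <- table(unique(arb[, c("neuron_id", "class")])$class)
  expect_equal(as.integer(cls[c("E-PG", "P-EG", "P-EN", "Delta7")]),
               c(18L, 18L, 16L, 8L))
  # P-EG_9 closes the ring: input G9, output T1
  peg9 <- subset(arb, neuron_id == "P-EG_9_L")
  expect_equal(peg9$index[peg9$polarity == "output"], 1L)
  expect_equal(peg9$volume_kind[peg9$polarity == "output"], "EB-tile")
  expect_equal(peg9$index[peg9$polarity == "input"], 9L)
  # P-EN_1 is unpaired: left G1 to T2; P-EN_9 right G9 to T8
  pen1 <- subset(arb, neuron_id == "P-EN_1_L")
  expect_equal(pen1$index[pen1$polarity == "output"], 2L)
  expect_false("P-EN_1_R" %in% arb$neuron_id)
  pen9 <- subset(arb, neuron_id == "P-EN_9_R")
  expect_equal(pen9$index[pen9$polarity == "output"], 8L)
  expect_false("P-EN_9_L" %in% arb$neuron_id)
  # Delta7 terminals all in the PB; outputs separated by seven glomeruli
  d7 <- subset(arb, class == "Delta7")
  expect_true(all(d7$volume_kind == "PB-glomerulus"))
  pos <- function(h, i) ifelse(h == "L", i, i + 9L)
  for (n in 1:8) {
    out <- subset(d7, neuron_id == sprintf("Delta7_%d", n) & polarity == "output")
    p <- sort(pos(out$hemisphere, out$index))
    expect_true(all(diff(p) == 8L)) # 7 glomeruli between consecutive domains
    expect_true(length(p) %in% 2:3)
  }
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_arbors_csv(arb, f)
  expect_equal(as.data.frame(read_arbors_csv(f)), as.data.frame(arb))
})

test_that("synapse inference links overlapping terminals with class signs", {
  g <- infer_synapses(cx_arbors())
  e <- g$edges
  expect_false(any(e$pre == e$post)) # no self-edges
  # signs follow the presynaptic class
  cls <- setNames(g$neurons$class, g$neurons$neuron_id)
  expect_true(all(e$sign[cls[e$pre] == "Delta7"] == -1))
  expect_true(all(e$sign[cls[e$pre] != "Delta7"] == 1))
  # E-PG_1_L excites every Delta7 with an input in left G1 (all but Delta7_1)
  tgt <- sort(e$post[e$pre == "E-PG_1_L" & cls[e$post] == "Delta7"])
  expect_equal(tgt, sort(sprintf("Delta7_%d", 2:8)))
  # neurons with disjoint volumes are unconnected: P-EG (PB in, EB out)
  # never contacts another P-EG
  expect_false(any(cls[e$pre] == "P-EG" & cls[e$post] == "P-EG"))
  # arbors lacking a terminal type are rejected
  bad <- cx_arbors()
  bad <- bad[!(bad$neuron_id == "P-EG_1_L" & bad$polarity == "output"), ]
  expect_error(infer_synapses(bad), "input and output")
})

test_that("reduction yields the eight-fold effective circuit", {
  cir <- fly_circuit()
  counts <- table(cir$units$class)
  expect_equal(as.integer(counts[c("E-PG", "P-EG", "P-EN", "Delta7")]),
               c(8L, 8L, 16L, 8L))
  expect_equal(sum(cir$units$class == "P-EN" & cir$units$laterality == "L"), 8L)
  expect_equal(sum(cir$units$class == "P-EN" & cir$units$laterality == "R"), 8L)
  # hemispheric P-EG_1 copies merged into one unit together with P-EG_9
  m <- cir$members[["P-EG_1"]]
  expect_true(all(c("P-EG_1_L", "P-EG_1_R", "P-EG_9_L", "P-EG_9_R") %in% m))
  expect_true(all(c("E-PG_1_L", "E-PG_1_R", "E-PG_9_L", "E-PG_9_R") %in%
                    cir$members[["E-PG_1"]]))
  # Delta7 block: all-to-all inhibition without self-edges (56 edges)
  cls <- setNames(cir$units$class, cir$units$unit)
  d7 <- cir$edges[cls[cir$edges$pre] == "Delta7" & cls[cir$edges$post] == "Delta7", ]
  expect_equal(nrow(d7), 56L)
  expect_true(all(d7$sign == -1))
  # every E-PG unit excites all 8 Delta7 units (64 edges)
  ed <- cir$edges[cls[cir$edges$pre] == "E-PG" & cls[cir$edges$post] == "Delta7", ]
  expect_equal(nrow(ed), 64L)
  # each P-EN pair at octant k reaches E-PG at octants k-1 and k+1
  oct <- setNames(cir$units$octant, cir$units$unit)
  pe <- cir$edges[cls[cir$edges$pre] == "P-EN" & cls[cir$edges$post] == "E-PG", ]
  shift <- ((oct[pe$post] - oct[pe$pre] + 4) %% 8) - 4
  expect_setequal(unique(shift), c(-1, 1))
  for (k in 1:8) # one left (+1) and one right (-1) P-EN edge per octant
    expect_equal(unname(sort(shift[oct[pe$pre] == k])), c(-1, 1))
})

test_that("reduction is idempotent and merges a constructed micro-fixture", {
  cir <- fly_circuit()
  again <- reduce_circuit(cir)
  expect_equal(again$units, cir$units)
  expect_equal(again$edges, cir$edges)
  # two identically connected neurons + one distinct -> 2 units
  mini <- reduce_circuit(infer_synapses(micro_arbors()))
  expect_equal(nrow(mini$units), 2L)
  expect_setequal(unlist(mini$members), micro_arbors()$neuron_id)
})

test_that("connectivity matrix maps edge classes to tied weights", {
  cir <- fly_circuit()
  # all-zero weights give the zero matrix
  expect_true(all(connectivity_matrix(cir, cx_weights(0, 0, 0, 0, 0)) == 0))
  w <- cx_weights(1, 2, 3, -4, -5)
  M <- connectivity_matrix(cir, w)
  expect_equal(dim(M), c(40L, 40L))
  expect_equal(sum(M != 0), nrow(cir$edges))
  # Delta7 rows carry inhibition only where Delta7 is presynaptic
  d7 <- grepl("^Delta7", rownames(M))
  expect_true(all(M[d7, ] <= 0))
  expect_true(all(M[!d7, ] >= 0))
  expect_equal(sum(M[d7, d7] < 0), 56L)
  expect_true(all(diag(M[d7, d7]) == 0))
  # octant rotation conjugation leaves M elementwise invariant
  u <- attr(M, "units")
  rot <- match(paste(u$class, ((u$octant %% 8) + 1), u$laterality),
               paste(u$class, u$octant, u$laterality))
  P <- diag(40)[rot, ]
  expect_equal(unname(t(P) %*% M %*% P), unname(M), ignore_attr = TRUE)
  # unmapped edge class pairs are rejected
  bad <- cir
  bad$edges <- rbind(bad$edges,
                     data.frame(pre = "E-PG_1", post = "E-PG_2", sign = 1))
  expect_error(connectivity_matrix(bad, w), "no weight parameter")
})

test_that("radial symmetry detection: full ring 8, broken edge 1", {
  cir <- fly_circuit()
  expect_identical(check_radial_symmetry(cir), 8L)
  broken <- cir
  broken$edges <- broken$edges[-1, ]
  expect_identical(check_radial_symmetry(broken), 1L)
})

test_that("circuit exports to GraphML, DOT and labelled CSV", {
  cir <- fly_circuit()
  f <- tempfile(fileext = ".graphml")
  write_circuit_graphml(cir, f, weights = cx_weights(1, 1, 1, -1, -1))
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 40)
  expect_equal(igraph::gsize(g), 200)
  expect_true("class" %in% igraph::vertex_attr_names(g))
  d <- tempfile(fileext = ".dot")
  write_circuit_dot(cir, d)
  expect_true(any(grepl("->", readLines(d))))
  m <- tempfile(fileext = ".csv")
  write_matrix_csv(connectivity_matrix(cir, cx_weights(1, 1, 1, -1, -1)), m)
  got <- read.csv(m, row.names = 1)
  expect_equal(dim(got), c(40L, 40L))
})
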