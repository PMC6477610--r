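# Network builders, validation, and serialization round trips.

params <- default_parameter_table()

test_that("rhythm generator builder produces the four-neuron half-center", {
  rg <- build_rhythm_generator("left", params)
  expect_length(rg$neurons, 4)
  roles <- vapply(rg$neurons, `[[`, character(1), "role")
  expect_equal(as.vector(sort(table(roles))), c(2, 2))
  # direct mutual connection is excitatory
  direct <- Filter(function(s) s$pre == "L_limb_RG_EXT" &&
                     s$post == "L_limb_RG_FLX", rg$synapses)
  expect_length(direct, 1)
  expect_equal(direct[[1]]$sign, "excitatory")
  # the interneuron path ends inhibitory
  to_in <- Filter(function(s) s$pre == "L_limb_RG_EXT" &&
                    s$post == "L_limb_IN_EXT", rg$synapses)
  in_to <- Filter(function(s) s$pre == "L_limb_IN_EXT" &&
                    s$post == "L_limb_RG_FLX", rg$synapses)
  expect_length(to_in, 1)
  expect_equal(in_to[[1]]$sign, "inhibitory")
  # oscillator neurons carry persistent sodium, interneurons do not
  expect_gt(rg$neurons[["L_limb_RG_EXT"]]$params$G_Na, 0)
  expect_equal(rg$neurons[["L_limb_IN_EXT"]]$params$G_Na, 0)
  expect_equal(nrow(validate_network(rg)), 0)
})

test_that("validation reports structural defects", {
  rg <- build_rhythm_generator("left", params)
  # removing both interneuron pathways leaves no inhibitory loop
  stripped <- network_spec(unname(rg$neurons),
                           Filter(function(s) s$sign == "excitatory",
                                  rg$synapses))
  d <- validate_network(stripped)
  expect_true(any(grepl("inhibitory loop", d$message)))
  # synapse to an unknown neuron is named in the diagnostic
  bad <- rg
  bad$synapses <- c(bad$synapses, list(structure(
    list(pre = "L_limb_RG_EXT", post = "GHOST",
         params = synapse_params(0.1, -10, -60, -40), sign = "excitatory"),
    class = "synapse_spec")))
  d2 <- validate_network(bad)
  expect_true(any(d2$item == "GHOST"))
  # persistent sodium on an interneuron draws a warning diagnostic
  warped <- rg
  warped$neurons[["L_limb_IN_EXT"]]$params <-
    params$neurons$RG_osc
  d3 <- validate_network(warped)
  expect_true(any(d3$level == "warning" & d3$item == "L_limb_IN_EXT"))
  # inconsistent sign vs reversal potential is an error
  flip <- rg
  flip$synapses[[1]]$sign <- "inhibitory"
  expect_true(any(validate_network(flip)$level == "error"))
})

test_that("pattern formation groups have mutual inhibition; kneeankle is shared", {
  pf <- build_pattern_formation("kneeankle", "left", params)
  expect_length(pf$neurons, 4)
  expect_true(all(c("L_kneeankle_PF_EXT", "L_kneeankle_PF_FLX") %in%
                    neuron_names(pf)))
  # an inhibitory path exists in both directions (via the interneurons)
  d <- validate_network(pf)
  expect_false(any(grepl("inhibitory loop", d$message)))
  expect_error(build_pattern_formation("elbow", "left", params))
})

test_that("motoneuron layer pairs each motoneuron with a Renshaw cell", {
  mn <- build_motoneuron_layer("knee", "left", params)
  expect_length(mn$neurons, 4)
  for (pol in c("EXT", "FLX")) {
    mnn <- paste0("L_knee_MN_", pol)
    ren <- paste0("L_knee_RE_", pol)
    fwd <- Filter(function(s) s$pre == mnn && s$post == ren, mn$synapses)
    back <- Filter(function(s) s$pre == ren && s$post == mnn, mn$synapses)
    expect_equal(fwd[[1]]$sign, "excitatory")
    expect_equal(back[[1]]$sign, "inhibitory")
  }
})

test_that("limb composition wires six motoneurons with a shared knee-ankle group", {
  limb <- build_limb("left", params)
  mns <- Filter(function(n) n$role == "MN", limb$neurons)
  expect_length(mns, 6)
  # knee and ankle extensor motoneurons receive from the same PF neuron
  pre_of <- function(post) vapply(
    Filter(function(s) s$post == post && s$sign == "excitatory",
           limb$synapses), `[[`, character(1), "pre")
  knee_src <- pre_of("L_knee_MN_EXT")
  ankle_src <- pre_of("L_ankle_MN_EXT")
  expect_true("L_kneeankle_PF_EXT" %in% knee_src)
  expect_equal(sort(knee_src[grepl("PF", knee_src)]),
               sort(ankle_src[grepl("PF", ankle_src)]))
  expect_equal(nrow(validate_network(limb)), 0)
  # two limbs are disjoint: no shared neurons, no crossing synapse
  both <- merge_networks(build_limb("left", params),
                         build_limb("right", params))
  left_names <- neuron_names(build_limb("left", params))
  crossing <- Filter(function(s)
    xor(s$pre %in% left_names, s$post %in% left_names), both$synapses)
  expect_length(crossing, 0)
  # composition collision raises
  expect_error(merge_networks(build_limb("left", params),
                              build_limb("left", params)), "duplicate")
})

test_that("single-joint baseline synapses the half-center directly onto motoneurons", {
  base <- build_single_joint_baseline("left", params)
  direct <- Filter(function(s) s$pre == "L_limb_RG_EXT" &&
                     s$post == "L_hip_MN_EXT", base$synapses)
  expect_length(direct, 1)
  expect_false(any(grepl("PF", neuron_names(base))))
  expect_equal(nrow(validate_network(base)), 0)
})

test_that("builders are deterministic and do not mutate their inputs", {
  a <- build_two_layer_cpg("left", params)
  b <- build_two_layer_cpg("left", params)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".yaml"); f2 <- tempfile(fileext = ".yaml")
  write_network(a, f1); write_network(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("network serialization round-trips losslessly (YAML and JSON)", {
  net <- build_limb("left", params)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_network(net, f)
    back <- read_network(f)
    expect_equal(back$neurons, net$neurons, tolerance = 1e-12)
    expect_equal(back$synapses, net$synapses, tolerance = 1e-12)
    # load -> save -> load is stable
    f2 <- tempfile(fileext = ext)
    write_network(back, f2)
    expect_equal(read_network(f2), back)
  }
})
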