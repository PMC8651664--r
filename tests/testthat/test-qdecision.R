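# Quantum decision layer: dose register, controller circuit, CU3
# stochasticity, Grover amplification, dose selection and OpenQASM.

test_that("dose grid has 2^n evenly spaced levels with bijective indexing", {
  g <- build_dose_grid(5, 1.0, 4.1)
  expect_length(g$levels, 32L)
  expect_equal(diff(g$levels), rep(3.1 / 31, 31))
  g1 <- build_dose_grid(1, 1, 2)
  expect_equal(g1$levels, c(1, 2))
  expect_error(build_dose_grid(5, 3, 2), class = "qdrlart_config_error")
  for (i in c(0L, 5L, 21L, 31L)) {
    expect_equal(bits_to_index(index_to_bits(i, 5)), i)
  }
  expect_equal(index_to_bits(21, 5), "10101")
  expect_error(bits_to_index("10102"), class = "qdrlart_domain_error")
})

test_that("noiseless controller returns the marked state for all n <= 4", {
  for (n in 1:4) {
    for (idx in 0:(2^n - 1)) {
      marked <- index_to_bits(idx, n)
      circ <- build_controller_circuit(marked)
      expect_equal(circ$n_qubits, 2L * n)
      p <- qdrlart:::measurement_probs(circ)
      expect_equal(p[idx + 1L], 1, tolerance = 1e-12)
    }
  }
  res <- simulate_circuit(build_controller_circuit("10101"), shots = 1024L)
  expect_equal(unname(res$counts["10101"]), 1024L)
  expect_equal(res$selected_index, 21L)
  expect_error(build_controller_circuit("012"), class = "qdrlart_domain_error")
})

test_that("controller layer structure is constant in the register width", {
  for (n in c(1, 3, 5, 8)) {
    circ <- build_controller_circuit(paste(rep("1", n), collapse = ""))
    expect_equal(circ$n_layers, 4L)
    # gate count grows linearly (<= 4n) but the layer count does not
    expect_lte(length(circ$gates), 4L * n)
  }
})

test_that("statevector stays normalized after every gate", {
  circ <- build_controller_circuit("1011",
                                   cu3_angles = list(theta = pi / 3, phi = 0.4,
                                                     lambda = 1.1))
  state <- qdrlart:::qstate_zero(circ$n_qubits)
  for (g in circ$gates) {
    state <- switch(g$type,
      x = qdrlart:::apply_gate(state, circ$n_qubits, qdrlart:::gate_x(), g$target),
      cx = qdrlart:::apply_gate(state, circ$n_qubits, qdrlart:::gate_x(),
                                g$target, g$control),
      cu3 = qdrlart:::apply_gate(state, circ$n_qubits,
                                 gate_u3(g$theta, g$phi, g$lambda),
                                 g$target, g$control))
    expect_equal(sum(Mod(state)^2), 1, tolerance = 1e-9)
  }
})

test_that("CU3(pi, 0, pi) reduces to CNOT and theta sets the flip rate", {
  ref <- qdrlart:::measurement_probs(build_controller_circuit("101"))
  cu <- qdrlart:::measurement_probs(build_controller_circuit(
    "101", cu3_angles = list(theta = pi, phi = 0, lambda = pi)))
  expect_equal(cu, ref, tolerance = 1e-12)
  # theta = pi/2 on a 1-qubit register: the entangling gate fires only on a
  # marked "1" control, flipping the main with probability sin^2(theta/4*2)
  circ <- build_controller_circuit("1",
                                   cu3_angles = list(theta = pi / 2, phi = 0,
                                                     lambda = 0))
  p <- qdrlart:::measurement_probs(circ)
  expect_equal(p[2], sin(pi / 4)^2, tolerance = 1e-12)
  set.seed(31)
  res <- simulate_circuit(circ, shots = 1e5)
  expect_equal(unname(res$counts["1"]) / 1e5, 0.5, tolerance = 0.01)
})

test_that("Grover amplification matches the closed form", {
  for (n in 1:5) {
    N <- 2^n
    theta <- asin(1 / sqrt(N))
    for (k in 0:6) {
      amp <- grover_amplify(n, marked = N - 1L, k = k)
      expect_equal(sum(Mod(amp)^2), 1, tolerance = 1e-9)
      expect_equal(Mod(amp[N])^2, sin((2 * k + 1) * theta)^2, tolerance = 1e-9)
      # unmarked amplitudes stay equal
      if (N > 2) expect_lt(diff(range(Mod(amp[1:(N - 2)]))), 1e-12)
    }
  }
  expect_equal(Mod(grover_amplify(2, 2, 1)[3])^2, 1, tolerance = 1e-12)
  expect_equal(Mod(grover_amplify(5, 7, 0)[8])^2, 1 / 32, tolerance = 1e-12)
  expect_error(grover_amplify(3, 8), class = "qdrlart_domain_error")
  expect_equal(grover_iterations(32), 4L)
})

test_that("select_dose is argmax under the noiseless controller with low-index ties", {
  grid <- build_dose_grid(5, 1.0, 4.1)
  q <- stats::rnorm(32)
  q[22] <- 10
  set.seed(1)
  d <- select_dose(q, grid)
  expect_equal(d$index, 21L)
  expect_equal(d$bits, "10101")
  expect_equal(d$dose, grid$levels[22])
  set.seed(1)
  tie <- select_dose(rep(0, 32), grid)
  expect_equal(tie$index, 0L)
  expect_error(select_dose(rep(0, 8), grid), class = "qdrlart_domain_error")
  expect_error(select_dose(q, grid, backend = "bogus"),
               class = "qdrlart_config_error")
})

test_that("Grover backend selects the argmax dose nearly always", {
  grid <- build_dose_grid(5, 1.0, 4.1)
  q <- stats::rnorm(32)
  q[14] <- 5
  # closed-form success probability at k = 4 is ~0.99918, so with 200 shots
  # per selection the argmax wins every of 50 repetitions
  set.seed(7)
  hits <- vapply(1:50, function(i) {
    select_dose(q, grid, backend = "grover-sim", shots = 200L)$index
  }, integer(1))
  expect_gte(mean(hits == 13L), 0.99)
})

test_that("external backends are invoked as counting functions", {
  grid <- build_dose_grid(3, 1, 2)
  fake_backend <- function(circuit, shots) {
    stats::setNames(c(shots - 1L, 1L), c(circuit$marked, "000"))
  }
  d <- select_dose(c(rep(0, 5), 3, 0, 0), grid, backend = fake_backend)
  expect_equal(d$index, 5L)
})

test_that("OpenQASM export has the expected structure and round-trips", {
  circ <- build_controller_circuit("101")
  txt <- export_qasm(circ)
  expect_match(txt, "OPENQASM 2.0;", fixed = TRUE)
  expect_match(txt, "qreg q\\[6\\];")
  expect_equal(lengths(regmatches(txt, gregexpr("\ncx ", txt))), 3L)
  back <- read_qasm(txt)
  expect_equal(qdrlart:::measurement_probs(back),
               qdrlart:::measurement_probs(circ))
  # cu3 gates survive the round trip with their angles
  cu <- build_controller_circuit("11", cu3_angles = list(theta = 0.7, phi = 0.1,
                                                         lambda = -0.3))
  txt2 <- export_qasm(cu)
  expect_match(txt2, "cu3(", fixed = TRUE)
  expect_equal(qdrlart:::measurement_probs(read_qasm(txt2)),
               qdrlart:::measurement_probs(cu), tolerance = 1e-12)
  # file round trip
  path <- withr::local_tempfile(fileext = ".qasm")
  export_qasm(circ, path)
  expect_equal(qdrlart:::measurement_probs(read_qasm(path)),
               qdrlart:::measurement_probs(circ))
})
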