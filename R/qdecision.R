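# Quantum decision layer. Doses live on an n-qubit register: each of the 2^n
# computational basis states is one eigen-dose. Selection of the greedy dose
# is performed either by the fixed-depth controller circuit (2n qubits,
# constant layer count for any n) or by Grover amplitude amplification, both
# simulated on an exact statevector. Bit convention: character 1 of a
# bitstring is the most significant bit of the dose index, and qubit 1 acts
# on that bit.

#' Build an evenly spaced dose grid on an n-qubit register
#'
#' @param n_qubits Number of qubits; the grid has `2^n_qubits` levels.
#' @param d_min,d_max Grid endpoints (Gy per fraction), inclusive.
#' @return A list of class `dose_grid` with elements `n_qubits`, `d_min`,
#'   `d_max` and `levels`.
#' @examples
#' build_dose_grid(5, 1.0, 4.1) # 32 levels, 0.1 Gy/frac spacing
#' @export
build_dose_grid <- function(n_qubits = 5L, d_min = 1.0, d_max = 4.1) {
  if (n_qubits < 1L) stop_config("n_qubits must be >= 1")
  if (d_min >= d_max) stop_config("d_min must be below d_max")
  n_levels <- 2L^as.integer(n_qubits)
  structure(
    list(n_qubits = as.integer(n_qubits), d_min = d_min, d_max = d_max,
         levels = seq(d_min, d_max, length.out = n_levels)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d qubits, %d levels in [%.3g, %.3g] Gy/frac\n",
              x$n_qubits, length(x$levels), x$d_min, x$d_max))
  invisible(x)
}

#' Convert between dose-grid indices and bitstrings
#'
#' Indices are 0-based over `2^n` levels; bitstrings are MSB-first, so index
#' 21 on 5 qubits is `"10101"`.
#'
#' @param index 0-based integer index.
#' @param n Number of qubits.
#' @param bits Character bitstring of `0`/`1`.
#' @return `index_to_bits` a bitstring; `bits_to_index` a 0-based integer.
#' @export
index_to_bits <- function(index, n) {
  if (index < 0 || index >= 2^n) stop_domain("index out of range for ", n, " qubits")
  paste(rev((as.integer(index) %/% 2^(0:(n - 1))) %% 2), collapse = "")
}

#' @rdname index_to_bits
#' @export
bits_to_index <- function(bits) {
  chars <- strsplit(bits, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% c("0", "1"))) {
    stop_domain("bitstring must be nonempty over {0,1}: ", bits)
  }
  sum(as.integer(chars) * 2^((length(chars) - 1):0))
}

# Statevector primitives -------------------------------------------------------

qstate_zero <- function(n_qubits) {
  v <- complex(2^n_qubits)
  v[1] <- 1 + 0i
  v
}

# bit of qubit q (1 = MSB) in 0-based index k, over m qubits
qubit_bit <- function(k, q, m) (k %/% 2^(m - q)) %% 2

# Apply a 2x2 unitary U to qubit `target`, optionally conditioned on qubit
# `control` being |1>. State indices are 0-based internally.
apply_gate <- function(state, m, U, target, control = NULL) {
  k <- 0:(length(state) - 1L)
  stride <- 2^(m - target)
  sel0 <- qubit_bit(k, target, m) == 0
  if (!is.null(control)) sel0 <- sel0 & qubit_bit(k, control, m) == 1
  i0 <- k[sel0] + 1L
  i1 <- i0 + stride
  a0 <- state[i0]
  a1 <- state[i1]
  state[i0] <- U[1, 1] * a0 + U[1, 2] * a1
  state[i1] <- U[2, 1] * a0 + U[2, 2] * a1
  state
}

gate_x <- function() matrix(c(0, 1, 1, 0), 2, 2)

#' Matrix of the U3 rotation gate
#'
#' `U3(theta, phi, lambda)` is the generic single-qubit rotation; controlled
#' on another qubit it becomes CU3, which reduces to CNOT at
#' `(theta, phi, lambda) = (pi, 0, pi)`. With a control always in `|1>`, the
#' target flips with probability `sin(theta / 2)^2`.
#'
#' @param theta,phi,lambda Euler angles (radians).
#' @return A 2x2 complex matrix.
#' @export
gate_u3 <- function(theta, phi, lambda) {
  matrix(c(
    complex(real = cos(theta / 2)),
    exp(1i * phi) * sin(theta / 2),
    -exp(1i * lambda) * sin(theta / 2),
    exp(1i * (phi + lambda)) * cos(theta / 2)
  ), 2, 2)
}

# Circuit objects --------------------------------------------------------------

#' Build the fixed-depth controller circuit for a marked basis state
#'
#' The circuit uses `2n` qubits split into a control register (qubits
#' `1..n`) and a main register (`n+1..2n`). Four gate layers, independent of
#' `n`: (1) pre-control X gates write the marked bitstring onto the control;
#' (2) a reverse layer of X gates flips every main qubit to `|1>`; (3) one
#' entangling CNOT per qubit pair (control i -> main i) flips exactly the
#' main qubits whose control is `|1>`, leaving the element-wise complement of
#' the marked string; (4) a second reverse layer restores the marked string
#' on the main register, which is then measured. Noiselessly the measurement
#' yields the marked state with probability 1. Supplying `cu3_angles`
#' replaces each CNOT with `CU3(theta, phi, lambda)`, injecting tunable
#' per-qubit stochasticity (flip probability `sin(theta/2)^2`).
#'
#' @param marked Bitstring of `0`/`1`, MSB first.
#' @param cu3_angles Optional list with elements `theta`, `phi`, `lambda`
#'   (scalars, or vectors of length `nchar(marked)`).
#' @return A list of class `qcircuit`.
#' @examples
#' build_controller_circuit("10101")
#' @export
build_controller_circuit <- function(marked, cu3_angles = NULL) {
  chars <- strsplit(marked, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% c("0", "1"))) {
    stop_domain("marked must be a nonempty bitstring over {0,1}: ", marked)
  }
  n <- length(chars)
  gates <- list()
  # layer 1: prepare the marked state on the control register
  for (i in seq_len(n)) {
    if (chars[i] == "1") gates[[length(gates) + 1L]] <- list(type = "x", target = i)
  }
  # layer 2: reverse gates on the main register
  for (i in seq_len(n)) {
    gates[[length(gates) + 1L]] <- list(type = "x", target = n + i)
  }
  # layer 3: entangle control -> main
  if (is.null(cu3_angles)) {
    for (i in seq_len(n)) {
      gates[[length(gates) + 1L]] <- list(type = "cx", control = i, target = n + i)
    }
  } else {
    th <- rep_len(cu3_angles$theta, n)
    ph <- rep_len(cu3_angles$phi, n)
    la <- rep_len(cu3_angles$lambda, n)
    for (i in seq_len(n)) {
      gates[[length(gates) + 1L]] <- list(type = "cu3", control = i, target = n + i,
                                          theta = th[i], phi = ph[i], lambda = la[i])
    }
  }
  # layer 4: second reverse layer before measurement
  for (i in seq_len(n)) {
    gates[[length(gates) + 1L]] <- list(type = "x", target = n + i)
  }
  structure(
    list(n_qubits = 2L * n, n_main = n, marked = marked, gates = gates,
         measure = (n + 1L):(2L * n), n_layers = 4L),
    class = "qcircuit"
  )
}

#' @export
print.qcircuit <- function(x, ...) {
  cat(sprintf("<qcircuit> %d qubits (%d measured), %d gates in %d layers",
              x$n_qubits, length(x$measure), length(x$gates), x$n_layers),
      if (!is.null(x$marked)) sprintf(", marked |%s>", x$marked) else "", "\n",
      sep = "")
  invisible(x)
}

# Exact statevector of the full register after all gates.
circuit_statevector <- function(circuit) {
  state <- qstate_zero(circuit$n_qubits)
  m <- circuit$n_qubits
  for (g in circuit$gates) {
    state <- switch(g$type,
      x = apply_gate(state, m, gate_x(), g$target),
      cx = apply_gate(state, m, gate_x(), g$target, g$control),
      cu3 = apply_gate(state, m, gate_u3(g$theta, g$phi, g$lambda),
                       g$target, g$control),
      stop_domain("unsupported gate type: ", g$type)
    )
  }
  state
}

# Marginal measurement distribution over the measured qubits.
measurement_probs <- function(circuit) {
  state <- circuit_statevector(circuit)
  m <- circuit$n_qubits
  probs_full <- Mod(state)^2
  k <- 0:(length(state) - 1L)
  meas <- circuit$measure
  out_index <- integer(length(k))
  for (j in seq_along(meas)) {
    out_index <- out_index + qubit_bit(k, meas[j], m) * 2^(length(meas) - j)
  }
  p <- as.numeric(tapply(probs_full, out_index, sum))
  full <- numeric(2^length(meas))
  full[sort(unique(out_index)) + 1L] <- p
  full
}

#' Simulate a circuit's measurement with a shot count
#'
#' Exact statevector simulation followed by multinomial sampling of the
#' measured register. The selected index is the most frequent outcome; count
#' ties break toward the lowest index.
#'
#' @param circuit A `qcircuit`.
#' @param shots Number of measurement shots (>= 1).
#' @return A list of class `measurement_result` with `counts` (named by
#'   bitstring, only observed outcomes), `shots`, `probs` and
#'   `selected_index` (0-based).
#' @export
simulate_circuit <- function(circuit, shots = 1024L) {
  if (shots < 1L) stop_domain("shots must be >= 1")
  p <- measurement_probs(circuit)
  draws <- as.integer(stats::rmultinom(1L, shots, p))
  n_meas <- length(circuit$measure)
  observed <- which(draws > 0L)
  counts <- draws[observed]
  names(counts) <- vapply(observed - 1L, index_to_bits, character(1), n = n_meas)
  structure(
    list(counts = counts, shots = as.integer(shots), probs = p,
         selected_index = which.max(draws) - 1L),
    class = "measurement_result"
  )
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf("<measurement_result> %d shots, selected index %d\n",
              x$shots, x$selected_index))
  print(x$counts)
  invisible(x)
}

#' Grover amplitude amplification over a dose register
#'
#' Starts from the uniform superposition over `N = 2^n` eigen-doses and
#' applies `k` Grover iterations (phase oracle on the marked index followed
#' by inversion about the mean). After `k` iterations the marked amplitude is
#' `sin((2k + 1) * asin(1 / sqrt(N)))` and the remaining amplitudes stay
#' equal.
#'
#' @param grid A [build_dose_grid()] (or an integer qubit count).
#' @param marked 0-based marked index.
#' @param k Number of Grover iterations (>= 0); default
#'   [grover_iterations()] of the register size.
#' @return Complex amplitude vector of length `N` with unit 2-norm.
#' @export
grover_amplify <- function(grid, marked, k = NULL) {
  n <- if (inherits(grid, "dose_grid")) grid$n_qubits else as.integer(grid)
  N <- 2L^n
  if (marked < 0 || marked >= N) stop_domain("marked index out of range")
  if (is.null(k)) k <- grover_iterations(N)
  if (k < 0) stop_domain("iteration count must be >= 0")
  amp <- rep(complex(real = 1 / sqrt(N)), N)
  for (i in seq_len(k)) {
    amp[marked + 1L] <- -amp[marked + 1L]     # phase oracle
    amp <- 2 * mean(amp) - amp                # inversion about the mean
  }
  amp
}

#' Default Grover iteration schedule
#'
#' @param N Register size.
#' @return `floor(pi / 4 * sqrt(N))`.
#' @export
grover_iterations <- function(N) as.integer(floor(pi / 4 * sqrt(N)))

#' Select an eigen-dose from q-values via the quantum layer
#'
#' Computes the greedy (argmax) index over the q-value vector — ties break
#' toward the lowest index — then amplifies and measures it with the chosen
#' mechanism. Under the noiseless controller backend the measured dose always
#' equals the greedy dose; the Grover backend samples the amplified
#' distribution, and CU3 angles on the controller inject per-qubit
#' stochasticity.
#'
#' @param q_values Numeric vector of length `length(grid$levels)`.
#' @param grid A [build_dose_grid()].
#' @param backend `"controller-sim"`, `"grover-sim"`, or a function
#'   `(circuit, shots) -> named counts` implementing an external executor.
#' @param shots Measurement shots.
#' @param cu3_angles Optional CU3 angle list forwarded to the controller
#'   circuit.
#' @return A list of class `dose_decision`: `index` (0-based), `bits`,
#'   `dose` (Gy/frac), `greedy_index`, `counts`.
#' @export
select_dose <- function(q_values, grid, backend = "controller-sim",
                        shots = 1024L, cu3_angles = NULL) {
  N <- length(grid$levels)
  if (length(q_values) != N) {
    stop_domain("q_values length ", length(q_values), " does not match grid size ", N)
  }
  greedy <- which.max(q_values) - 1L   # which.max already breaks ties low
  if (is.function(backend)) {
    circuit <- build_controller_circuit(index_to_bits(greedy, grid$n_qubits),
                                        cu3_angles = cu3_angles)
    counts <- backend(circuit, shots)
    sel <- bits_to_index(names(counts)[which.max(counts)])
  } else if (backend == "controller-sim") {
    circuit <- build_controller_circuit(index_to_bits(greedy, grid$n_qubits),
                                        cu3_angles = cu3_angles)
    res <- simulate_circuit(circuit, shots)
    sel <- res$selected_index
    counts <- res$counts
  } else if (backend == "grover-sim") {
    amp <- grover_amplify(grid, greedy)
    draws <- as.integer(stats::rmultinom(1L, shots, Mod(amp)^2))
    sel <- which.max(draws) - 1L
    observed <- which(draws > 0L)
    counts <- draws[observed]
    names(counts) <- vapply(observed - 1L, index_to_bits, character(1),
                            n = grid$n_qubits)
  } else {
    stop_config("unknown backend: ", backend)
  }
  structure(
    list(index = sel, bits = index_to_bits(sel, grid$n_qubits),
         dose = grid$levels[sel + 1L], greedy_index = greedy, counts = counts),
    class = "dose_decision"
  )
}

#' @export
print.dose_decision <- function(x, ...) {
  cat(sprintf("<dose_decision> |%s> = index %d = %.3f Gy/frac (greedy %d)\n",
              x$bits, x$index, x$dose, x$greedy_index))
  invisible(x)
}

# OpenQASM 2.0 -----------------------------------------------------------------

#' Export a circuit to OpenQASM 2.0
#'
#' Qubit `i` of the circuit maps to `q[i - 1]`; measured qubits map in order
#' onto the classical register. Re-importing with [read_qasm()] and
#' simulating reproduces the measurement distribution.
#'
#' @param circuit A `qcircuit`.
#' @param path Optional file path; when given the text is also written there.
#' @return The QASM program as a character scalar.
#' @export
export_qasm <- function(circuit, path = NULL) {
  lines <- c(
    "OPENQASM 2.0;",
    'include "qelib1.inc";',
    sprintf("qreg q[%d];", circuit$n_qubits),
    sprintf("creg c[%d];", length(circuit$measure))
  )
  for (g in circuit$gates) {
    lines <- c(lines, switch(g$type,
      x = sprintf("x q[%d];", g$target - 1L),
      cx = sprintf("cx q[%d],q[%d];", g$control - 1L, g$target - 1L),
      cu3 = sprintf("cu3(%.17g,%.17g,%.17g) q[%d],q[%d];",
                    g$theta, g$phi, g$lambda, g$control - 1L, g$target - 1L),
      stop_domain("cannot export gate type: ", g$type)
    ))
  }
  for (j in seq_along(circuit$measure)) {
    lines <- c(lines, sprintf("measure q[%d] -> c[%d];",
                              circuit$measure[j] - 1L, j - 1L))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(text, path, sep = "")
  text
}

#' Read an OpenQASM 2.0 circuit (the gate subset this package emits)
#'
#' Supports `x`, `cx`, `cu3` gates and `measure` statements on a single
#' quantum register.
#'
#' @param text QASM program text, or a file path to one.
#' @return A `qcircuit`.
#' @export
read_qasm <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  lines <- trimws(strsplit(text, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  n_qubits <- NA_integer_
  gates <- list()
  measure <- integer(0)
  for (ln in lines) {
    if (grepl("^(OPENQASM|include|creg)", ln)) next
    if (grepl("^qreg", ln)) {
      n_qubits <- as.integer(sub("^qreg q\\[(\\d+)\\];$", "\\1", ln))
    } else if (grepl("^x ", ln)) {
      q <- as.integer(sub("^x q\\[(\\d+)\\];$", "\\1", ln))
      gates[[length(gates) + 1L]] <- list(type = "x", target = q + 1L)
    } else if (grepl("^cx ", ln)) {
      m <- regmatches(ln, regexec("^cx q\\[(\\d+)\\],q\\[(\\d+)\\];$", ln))[[1]]
      gates[[length(gates) + 1L]] <- list(type = "cx",
                                          control = as.integer(m[2]) + 1L,
                                          target = as.integer(m[3]) + 1L)
    } else if (grepl("^cu3", ln)) {
      m <- regmatches(ln, regexec(
        "^cu3\\(([^,]+),([^,]+),([^)]+)\\) q\\[(\\d+)\\],q\\[(\\d+)\\];$", ln))[[1]]
      gates[[length(gates) + 1L]] <- list(type = "cu3",
                                          control = as.integer(m[5]) + 1L,
                                          target = as.integer(m[6]) + 1L,
                                          theta = as.numeric(m[2]),
                                          phi = as.numeric(m[3]),
                                          lambda = as.numeric(m[4]))
    } else if (grepl("^measure", ln)) {
      m <- regmatches(ln, regexec("^measure q\\[(\\d+)\\] -> c\\[(\\d+)\\];$", ln))[[1]]
      measure[as.integer(m[3]) + 1L] <- as.integer(m[2]) + 1L
    } else {
      stop_domain("unsupported QASM statement: ", ln)
    }
  }
  if (is.na(n_qubits)) stop_domain("QASM program lacks a qreg declaration")
  structure(
    list(n_qubits = n_qubits, n_main = length(measure), marked = NULL,
         gates = gates, measure = measure, n_layers = NA_integer_),
    class = "qcircuit"
  )
}
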