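# Shared builders and independent numerical oracles for the test suite.

avg_params <- load_parameters("average")
seq_params <- load_parameters("sequence_dependent")

rotate_vec <- function(v, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  cx <- c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1])
  v * cos(theta) + cx * sin(theta) + axis * sum(axis * v) * (1 - cos(theta))
}

# random small perturbation of a configuration's poses (keeps frames
# orthonormal by construction)
perturb_config <- function(cfg, sd_pos = 0.05, sd_rot = 0.1) {
  n <- nrow(cfg$com)
  cfg$com <- cfg$com + matrix(rnorm(3 * n, sd = sd_pos), n, 3)
  for (i in seq_len(n)) {
    ax <- rnorm(3)
    th <- rnorm(1, sd = sd_rot)
    cfg$a1[i, ] <- rotate_vec(cfg$a1[i, ], ax, th)
    cfg$a3[i, ] <- rotate_vec(cfg$a3[i, ], ax, th)
  }
  cfg
}

rotate_config_global <- function(cfg, axis, theta) {
  n <- nrow(cfg$com)
  for (i in seq_len(n)) {
    cfg$com[i, ] <- rotate_vec(cfg$com[i, ], axis, theta)
    cfg$a1[i, ] <- rotate_vec(cfg$a1[i, ], axis, theta)
    cfg$a3[i, ] <- rotate_vec(cfg$a3[i, ], axis, theta)
    cfg$vel[i, ] <- rotate_vec(cfg$vel[i, ], axis, theta)
    cfg$ang[i, ] <- rotate_vec(cfg$ang[i, ], axis, theta)
  }
  cfg
}

# central-difference force/torque oracle (independent of the analytic path)
numerical_gradients <- function(cfg, params, h = 1e-6) {
  n <- nrow(cfg$com)
  force <- matrix(0, n, 3); torque <- matrix(0, n, 3)
  axes <- diag(3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      cp <- cfg; cp$com[i, d] <- cp$com[i, d] + h
      cm <- cfg; cm$com[i, d] <- cm$com[i, d] - h
      force[i, d] <- -(total_energy(cp, params)$energy$total -
                       total_energy(cm, params)$energy$total) / (2 * h)
      cp <- cfg
      cp$a1[i, ] <- rotate_vec(cfg$a1[i, ], axes[d, ], h)
      cp$a3[i, ] <- rotate_vec(cfg$a3[i, ], axes[d, ], h)
      cm <- cfg
      cm$a1[i, ] <- rotate_vec(cfg$a1[i, ], axes[d, ], -h)
      cm$a3[i, ] <- rotate_vec(cfg$a3[i, ], axes[d, ], -h)
      torque[i, d] <- -(total_energy(cp, params)$energy$total -
                        total_energy(cm, params)$energy$total) / (2 * h)
    }
  }
  list(force = force, torque = torque)
}

# brute-force monotonicity oracle for pseudoknot detection
brute_pseudoknot <- function(pairs) {
  if (nrow(pairs) < 2) return(FALSE)
  j <- pairs$j[order(pairs$i)]
  !(all(diff(j) < 0) || all(diff(j) > 0))
}

# structure sequences mimicking the canonical internal-displacement
# trajectories on the 14-mer repeats (register conventions as in the
# package: pair (i, j) has register j - (13 - i))
mk_struct <- function(df, n = 14) secondary_structure(df, n)

pairs_in_register <- function(r, i_range, n = 14) {
  i <- i_range
  j <- n - 1 - i + r
  ok <- j >= 0 & j <= n - 1
  data.frame(i = i[ok], j = j[ok])
}

rep_frames <- function(struct, k) rep(list(struct), k)

zippering_record <- function(dwell = 12) {
  frames <- list(mk_struct(NULL))
  for (k in 1:14) {
    st <- mk_struct(pairs_in_register(0, (14 - k):13))
    frames <- c(frames, rep_frames(st, dwell))
  }
  transition_record(frames)
}

inchworm_record <- function(dwell = 12) {
  s_start <- mk_struct(pairs_in_register(4, 4:13))             # 10 bp, r = 4
  s_bulge <- mk_struct(rbind(pairs_in_register(4, 4:10),        # bulge forms
                             pairs_in_register(0, 11:13)))
  s_mid <- mk_struct(rbind(pairs_in_register(4, 4:7),           # bulge migrates
                           pairs_in_register(0, 8:13)))
  s_done <- mk_struct(pairs_in_register(0, 0:13))               # full duplex
  transition_record(c(rep_frames(s_start, dwell), rep_frames(s_bulge, dwell),
                      rep_frames(s_mid, dwell), rep_frames(s_done, dwell)))
}

pseudoknot_record <- function(dwell = 12) {
  s_start <- mk_struct(pairs_in_register(10, 10:13))            # r = 10 duplex
  s_pk <- mk_struct(rbind(pairs_in_register(10, 10:13),         # tails bind r=0
                          pairs_in_register(0, 4:9)))
  s_more <- mk_struct(rbind(pairs_in_register(10, 13),          # r = 10 recedes
                            pairs_in_register(0, c(2, 4:9))))
  s_done <- mk_struct(pairs_in_register(0, 0:13))
  transition_record(c(rep_frames(s_start, dwell), rep_frames(s_pk, dwell),
                      rep_frames(s_more, dwell), rep_frames(s_done, dwell)))
}

detachment_record <- function(dwell = 12) {
  s_start <- mk_struct(pairs_in_register(-8, 0:5))
  s_less <- mk_struct(pairs_in_register(-8, 0:2))
  s_off <- mk_struct(NULL)
  transition_record(c(rep_frames(s_start, dwell), rep_frames(s_less, dwell),
                      rep_frames(s_off, dwell)))
}
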