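# Shared fixtures and the independent per-layer closed-form ledger used to
# cross-check the package's parameter / FLOP accounting.

# write a temporary recording CSV with the given channels and return its path
write_fixture_csv <- function(channels, path = tempfile(fileext = ".csv")) {
  df <- as.data.frame(channels)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a deterministic sinusoidal recording of n samples
fixture_recording <- function(n, condition = "baseline", subject = "S01",
                              fs = 10) {
  t <- (seq_len(n) - 1) / fs
  nirs_recording(list(O2Hb = sin(2 * pi * 0.25 * t),
                      HHb = -0.4 * sin(2 * pi * 0.25 * t)),
                 condition, subject, fs)
}

# labeled window set with the given per-class sizes, built through the
# public crop_windows API (one long recording per class)
fixture_windows <- function(class_sizes, window_len = 8L) {
  conds <- breathing_conditions()
  sets <- lapply(seq_along(class_sizes), function(i) {
    rec <- fixture_recording(class_sizes[i] * window_len,
                             condition = conds[i],
                             subject = sprintf("S%02d", i))
    crop_windows(rec, window_len)
  })
  nirsnet:::bind_windows(sets)
}

# Independent closed-form ledger: walks an explicit stage table (kernel,
# fan-in, fan-out, output length per conv) and sums k*Cin*Cout parameters
# and 2*k*Cin*Cout*Lout FLOPs.  Deliberately written from the architecture
# table, not from the package's model structure.
ledger_counts <- function(variant, blocks = 12L, input_channels = 1L,
                          num_classes = 3L,
                          input_length = if (variant == "ds") 32L else 64L) {
  rows <- list()
  add <- function(k, cin, cout, L, bn_in = NA) {
    rows[[length(rows) + 1L]] <<- c(k = k, cin = cin, cout = cout, L = L,
                                    bn = if (is.na(bn_in)) 0 else 2 * bn_in)
  }
  L <- input_length
  add(5, input_channels, 16, L)                       # stem, no preceding BN
  if (variant != "ds") {
    k1 <- if (variant == "stage1_k3") 3 else 5
    L <- L / 2
    add(1, 16, 16, L, bn_in = 16)
    add(k1, 16, 16, L, bn_in = 16)
    add(1, 16, 16, L, bn_in = 16)
  }
  stages <- list(list(w = 16, out = 64, stride = 1),
                 list(w = 32, out = 128, stride = 2),
                 list(w = 64, out = 256, stride = 2))
  cin <- 16
  for (st in stages) {
    L <- L / st$stride
    for (b in seq_len(blocks)) {
      add(1, cin, st$w, L, bn_in = cin)
      add(3, st$w, st$w, L, bn_in = st$w)
      add(1, st$w, st$out, L, bn_in = st$w)
      cin <- st$out
    }
  }
  tab <- do.call(rbind, rows)
  params <- sum(tab[, "k"] * tab[, "cin"] * tab[, "cout"]) +  # convs
    sum(tab[, "bn"]) +                                        # their BNs
    2 * 256 +                                                 # final BN
    256 * num_classes + num_classes                           # classifier
  flops <- sum(2 * tab[, "k"] * tab[, "cin"] * tab[, "cout"] * tab[, "L"]) +
    2 * 256 * num_classes
  list(params = params, flops = flops)
}
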