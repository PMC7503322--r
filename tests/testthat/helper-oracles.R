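# independent brute-force metric oracles over the raw event logs

oracle_metrics <- function(record) {
  ph <- record$phases; mv <- record$moves
  size <- record$grid$size
  do.call(rbind, lapply(sort(unique(ph$block)), function(b) {
    safes <- record$layouts[[b]]
    expl <- ph[ph$block == b & ph$phase == "explore", ]
    uniq <- 0; esc <- 0; moves <- 0; stress_t <- 0
    for (i in seq_len(nrow(expl))) {
      ev <- mv[mv$block == b & mv$trial == expl$trial[i] &
                 mv$phase == "explore", ]
      cells <- c(expl$start_row[i] * size + expl$start_col[i],
                 ev$row * size + ev$col)
      uniq <- uniq + length(unique(cells))
    }
    st <- ph[ph$block == b & ph$phase == "stress", ]
    for (i in seq_len(nrow(st))) {
      ev <- mv[mv$block == b & mv$trial == st$trial[i] &
                 mv$phase == "stress", ]
      moves <- moves + nrow(ev)
      # a stress phase can also end at t = 0 if it begins on a safe cell
      # (study 1 carries the exploration end position into the stress
      # phase); the raw logs then contain no move event for it
      start_safe <- (st$start_row[i] * size + st$start_col[i]) %in% safes
      escaped <- start_safe || any(ev$on_safe)
      esc <- esc + escaped
      stress_t <- stress_t + if (start_safe) 0 else if (any(ev$on_safe))
        min(ev$t[ev$on_safe]) else st$duration[i]
    }
    data.frame(block = b,
               exploration = uniq / (sum(expl$duration) / 60),
               escapes = esc,
               efficiency = if (esc > 0)
                 (moves / (stress_t / 60)) / esc else NA_real_)
  }))
}
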