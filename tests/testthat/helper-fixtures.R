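# Shared fixture builders. Everything is generated in code; no binary data.

# quick patient_record from a list of "date codes..." strings
rec <- function(pid, ...) {
  visits <- lapply(list(...), function(v) {
    parts <- strsplit(v, " ")[[1L]]
    list(date = as.Date(parts[1L]), codes = parts[-1L])
  })
  patient_record(pid, visits)
}

# random record with n_visits visits drawn from a small code pool
random_record <- function(pid, n_visits = 5L, pool = sprintf("%03d.0", 100:120),
                          start = as.Date("2015-01-01")) {
  dates <- sort(start + sample.int(400L, n_visits, replace = TRUE))
  patient_record(pid, lapply(seq_len(n_visits), function(i)
    list(date = dates[i],
         codes = sample(pool, sample.int(3L, 1L), replace = FALSE))))
}

tiny_vocab <- function(codes = sprintf("C%02d", 1:10)) dx_vocabulary(codes)

# the four-visit worked record written as a wide CSV table
worked_example_csv <- function(path) {
  writeLines(c("patient_id,date,dx1,dx2,dx3",
               "A,2013-11-11,250.0,,",
               "A,2013-11-21,726.0,438.5,847.0",
               "A,2013-12-05,250.0,,",
               "A,2013-12-09,414.0,401.9,250.0"), path)
  path
}
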