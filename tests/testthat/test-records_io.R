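test_that("corrections are parsed, self-loops dropped with a reason", {
  path <- write_tmp_csv(c("date,sender_id,receiver_id",
                          "2019-01-07,A,B",
                          "2019-01-08,B,B",
                          "2019-01-09,B,A"))
  ev <- read_corrections(path)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$date[1], as.Date("2019-01-07"))
  expect_equal(ev$sender_id[1], "A")
  expect_equal(ev$receiver_id[1], "B")
  rep <- attr(ev, "drop_report")
  expect_equal(rep$count[rep$reason == "self_loop"], 1L)
  expect_equal(attr(ev, "n_read"), 3L)
})

test_that("header-only file gives an empty event list", {
  path <- write_tmp_csv("date,sender_id,receiver_id")
  ev <- read_corrections(path)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "n_read"), 0L)
})

test_that("missing file and missing column are fatal", {
  expect_error(read_corrections(tempfile()), "not found")
  path <- write_tmp_csv(c("date,sender_id", "2019-01-07,A"))
  expect_error(read_corrections(path), "missing required column")
})

test_that("a column-name dialect maps non-canonical headers", {
  path <- write_tmp_csv(c("when,from,to", "2019-01-07,A,B"))
  ev <- read_corrections(path, dialect = c(date = "when", sender_id = "from",
                                           receiver_id = "to"))
  expect_equal(ev$sender_id, "A")
})

test_that("roster rows derive days_in_program; bad rosters are fatal", {
  path <- write_tmp_csv(c("resident_id,entry_date,exit_date,graduated,age,race_minority,lsi_r",
                          "R1,2019-01-01,2019-05-01,1,30,0,25"))
  ro <- read_roster(path)
  expect_equal(ro$days_in_program, 120)

  dup <- write_tmp_csv(c("resident_id,entry_date,exit_date,graduated,age,race_minority,lsi_r",
                         "R1,2019-01-01,2019-05-01,1,30,0,25",
                         "R1,2019-02-01,2019-06-01,0,40,1,30"))
  expect_error(read_roster(dup), "R1")

  rev <- write_tmp_csv(c("resident_id,entry_date,exit_date,graduated,age,race_minority,lsi_r",
                         "R1,2019-05-01,2019-01-01,1,30,0,25"))
  expect_error(read_roster(rev), "row")
})

test_that("missing covariate flags the record incomplete with a warning", {
  path <- write_tmp_csv(c("resident_id,entry_date,exit_date,graduated,age,race_minority,lsi_r",
                          "R1,2019-01-01,2019-05-01,1,30,0,",
                          "R2,2019-01-01,2019-04-01,0,25,1,20"))
  expect_warning(ro <- read_roster(path), "incomplete")
  expect_true(ro$incomplete[ro$resident_id == "R1"])
  expect_false(ro$incomplete[ro$resident_id == "R2"])
})

test_that("corrections and roster round-trip through CSV identically", {
  set.seed(11)
  sim <- simulate_unit(quick_sim())
  ep <- tempfile(fileext = ".csv"); rp <- tempfile(fileext = ".csv")
  write_corrections(sim$events, ep)
  write_roster(sim$roster, rp)
  ev2 <- read_corrections(ep)
  ro2 <- read_roster(rp)
  expect_equal(ev2$date, sim$events$date)
  expect_equal(ev2$sender_id, sim$events$sender_id)
  expect_equal(ev2$receiver_id, sim$events$receiver_id)
  expect_equal(ro2$resident_id, sim$roster$resident_id)
  expect_equal(ro2$days_in_program, sim$roster$days_in_program)
  expect_equal(ro2$graduated, sim$roster$graduated)
})

test_that("cross_validate drops unknown residents and out-of-tenure events", {
  roster <- data.frame(resident_id = c("A", "B"),
                       entry_date = as.Date(c("2019-01-01", "2019-01-01")),
                       exit_date = as.Date(c("2019-03-01", "2019-03-01")),
                       graduated = c(1L, 0L), age = c(30, 25),
                       race_minority = c(0L, 1L), lsi_r = c(25, 20),
                       days_in_program = c(59, 59), incomplete = FALSE)
  events <- data.frame(date = as.Date(c("2019-01-15", "2018-12-15", "2019-01-20")),
                       sender_id = c("A", "A", "Z"),
                       receiver_id = c("B", "B", "A"))
  v <- cross_validate(events, roster)
  expect_equal(v$report$n_events_dropped, 2)
  reasons <- v$report$drop_reasons
  expect_equal(reasons$count[reasons$reason == "out_of_tenure"], 1L)
  expect_equal(reasons$count[reasons$reason == "unknown_resident"], 1L)
  expect_equal(nrow(v$events), 1)

  # idempotence: a second pass drops nothing
  v2 <- cross_validate(v$events, roster)
  expect_equal(v2$report$n_events_dropped, 0)
  expect_equal(v2$events, v$events)
})

test_that("all-valid events pass through untouched", {
  set.seed(3)
  sim <- simulate_unit(quick_sim())
  v <- cross_validate(sim$events, sim$roster)
  expect_equal(v$report$n_events_dropped, 0)
  expect_equal(nrow(v$events), nrow(sim$events))
})
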