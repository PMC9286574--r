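# fixtures built in code: minimal traces used across test files

const_skin_trace <- function(temp = 35, t = 285:1260, bat_id = "b1",
                             date = "2018-08-01", mass = 8, ambient = NULL) {
  skin_trace(bat_id, date, t, rep_len(temp, length(t)), mass, ambient = ambient)
}

# logger trace with an arbitrary temperature function of minutes-of-day
fun_logger_trace <- function(f, dates = "2018-08-01", res = 10,
                             roost_id = "r1", substrate = "rock",
                             status = "used") {
  t_day <- seq(0, 1439, by = res)
  microhabitat_trace(roost_id, substrate, status,
                     rep(dates, each = length(t_day)),
                     rep(t_day, length(dates)),
                     unlist(lapply(seq_along(dates), function(i) f(t_day))))
}

# daytime ambient series on the 1-min window grid used by gen_skin_trace
flat_ambient <- function(temp = 20, t = 285:1260) data.frame(t = t, temp = rep(temp, length(t)))
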