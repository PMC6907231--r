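# Condition-grammar pattern table: units, qualitative tokens and separators
# used by the text interpreter. Extend without code changes.
time_units:
  s: s
  sec: s
  secs: s
  second: s
  seconds: s
  min: min
  mins: min
  minute: min
  minutes: min
  h: h
  hr: h
  hrs: h
  hour: h
  hours: h
  d: d
  day: d
  days: d
temp_units:
  "°C": "°C"
  "ºC": "°C"
  "oC": "°C"
  "C": "°C"
  "K": "K"
time_tokens: [overnight, o/n]
temp_tokens: [rt, r.t., r.t, reflux]
yield_words: [yield, yld]
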