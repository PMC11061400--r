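ch01:
  hemisphere: left
  mirror: 13
  region: PMC
ch02:
  hemisphere: left
  mirror: 14
  region: PMC
ch03:
  hemisphere: left
  mirror: 15
  region: PMC
ch04:
  hemisphere: left
  mirror: 16
  region: PMC
ch05:
  hemisphere: left
  mirror: 17
  region: M1
ch06:
  hemisphere: left
  mirror: 18
  region: M1
ch07:
  hemisphere: left
  mirror: 19
  region: M1
ch08:
  hemisphere: left
  mirror: 20
  region: M1
ch09:
  hemisphere: left
  mirror: 21
  region: S1
ch10:
  hemisphere: left
  mirror: 22
  region: S1
ch11:
  hemisphere: left
  mirror: 23
  region: S1
ch12:
  hemisphere: left
  mirror: 24
  region: S1
ch13:
  hemisphere: right
  mirror: 1
  region: PMC
ch14:
  hemisphere: right
  mirror: 2
  region: PMC
ch15:
  hemisphere: right
  mirror: 3
  region: PMC
ch16:
  hemisphere: right
  mirror: 4
  region: PMC
ch17:
  hemisphere: right
  mirror: 5
  region: M1
ch18:
  hemisphere: right
  mirror: 6
  region: M1
ch19:
  hemisphere: right
  mirror: 7
  region: M1
ch20:
  hemisphere: right
  mirror: 8
  region: M1
ch21:
  hemisphere: right
  mirror: 9
  region: S1
ch22:
  hemisphere: right
  mirror: 10
  region: S1
ch23:
  hemisphere: right
  mirror: 11
  region: S1
ch24:
  hemisphere: right
  mirror: 12
  region: S1
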