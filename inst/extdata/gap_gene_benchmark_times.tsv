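# Previously reported wall-clock run times for the gap-gene circuit
# reverse-engineering benchmark (48-50 optimisation runs per row on a
# compute cluster; times are mean H:MM to reach the target objective,
# half-widths hw_* are the printed 95% intervals on the mean).
# algorithm "serial" = serial island-ES (nodes column = island count);
# "sync"/"async" = synchronous/asynchronous parallel island-ES on the
# given number of nodes. good_enough: E* = 550000; good: E* = 350000.
# A ">" prefix marks runs that did not reach the target within the
# 36-hour job limit.
algorithm	nodes	time_good_enough	hw_good_enough	time_good	hw_good
serial	1	3:35	0:54	9:51	1:05
serial	2	3:49	0:42	10:27	1:01
serial	4	4:33	1:03	13:24	1:00
serial	8	7:30	2:08	28:02	0:47
serial	20	10:09	1:52	31:17	0:58
serial	50	16:03	1:39	>36:00	NA
sync	10	0:56	0:07	3:55	0:16
sync	20	0:41	0:03	4:09	0:14
sync	50	0:33	0:03	3:40	0:16
async	10	0:47	0:06	3:34	0:11
async	20	0:40	0:05	3:44	0:13
async	50	0:25	0:02	3:23	0:12
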