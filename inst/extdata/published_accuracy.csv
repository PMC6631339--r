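date,time,subject,algorithm,beep_interval_s,accuracy
03.09.2017,15:10,1,backprop,10,0.5975
03.09.2017,17:44,1,backprop,10,0.565
03.09.2017,18:11,1,backprop,5,0.4675
03.09.2017,18:20,1,backprop,5,0.56
03.09.2017,18:38,2,backprop,10,0.5975
03.09.2017,18:48,2,backprop,10,0.6
14.08.2018,10:06,4,backprop,10,0.54
17.08.2018,13:03,5,backprop,10,0.511
17.08.2018,13:28,6,backprop,10,0.52
17.08.2018,13:56,7,backprop,10,0.574
17.08.2018,20:13,8,backprop,10,0.5419
19.08.2018,12:33,9,backprop,10,0.5839
20.08.2018,18:15,10,backprop,10,0.515
20.08.2018,18:45,11,backprop,10,0.565
04.09.2017,22:32,1,rprop,10,0.5975
04.09.2017,22:40,1,rprop,10,0.5075
05.09.2017,22:09,2,rprop,10,0.5575
05.09.2017,22:17,2,rprop,10,0.52
04.09.2017,23:42,3,rprop,10,0.5575
14.08.2018,10:10,4,rprop,10,0.535
17.08.2018,13:15,5,rprop,10,0.524
17.08.2018,13:35,6,rprop,10,0.521
17.08.2018,14:01,7,rprop,10,0.56
17.08.2018,20:20,8,rprop,10,0.5575
19.08.2018,12:41,9,rprop,10,0.535
20.08.2018,18:20,10,rprop,10,0.525
20.08.2018,18:50,11,rprop,10,0.572
04.09.2017,22:52,1,levenberg_marquardt,10,0.6025
04.09.2017,23:04,1,levenberg_marquardt,10,0.66
05.09.2017,22:25,2,levenberg_marquardt,10,0.5675
05.09.2017,22:36,2,levenberg_marquardt,10,0.555
14.08.2018,10:03,4,levenberg_marquardt,10,0.544
17.08.2018,12:57,5,levenberg_marquardt,10,0.521
17.08.2018,13:20,6,levenberg_marquardt,10,0.56
17.08.2018,13:48,7,levenberg_marquardt,10,0.5875
17.08.2018,20:07,8,levenberg_marquardt,10,0.596
19.08.2018,12:23,9,levenberg_marquardt,10,0.55
20.08.2018,18:10,10,levenberg_marquardt,10,0.531
20.08.2018,18:37,11,levenberg_marquardt,10,0.601
20.08.2018,19:07,12,levenberg_marquardt,10,0.5503
05.09.2017,21:03,1,error_correction,10,0.505
05.09.2017,21:32,1,error_correction,10,0.4825
06.09.2017,22:00,2,error_correction,10,0.4975
06.09.2017,22:05,2,error_correction,10,0.4925
14.08.2018,10:15,4,error_correction,10,0.505
17.08.2018,13:24,5,error_correction,10,0.51
17.08.2018,13:40,6,error_correction,10,0.4975
17.08.2018,14:14,7,error_correction,10,0.505
17.08.2018,20:27,8,error_correction,10,0.5495
19.08.2018,12:50,9,error_correction,10,0.521
20.08.2018,18:26,10,error_correction,10,0.4984
20.08.2018,18:00,11,error_correction,10,0.521
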