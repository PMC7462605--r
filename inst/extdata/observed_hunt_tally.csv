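"hunt_id","date","catcher_group","prey","success"
"OBS_01",2016-08-22,"Ekalakala","anomalure",1
"OBS_02",2016-09-06,"Ekalakala","anomalure",1
"OBS_03",2016-09-08,"Ekalakala","anomalure",1
"OBS_04",2016-09-09,"Ekalakala","anomalure",1
"OBS_05",2016-10-23,"Ekalakala","anomalure",1
"OBS_06",2016-11-19,"Ekalakala","anomalure",1
"OBS_07",2016-12-07,"Ekalakala","anomalure",1
"OBS_08",2017-02-09,"Ekalakala","anomalure",1
"OBS_09",2017-04-05,"Ekalakala","anomalure",1
"OBS_10",2017-04-09,"Ekalakala","anomalure",1
"OBS_11",2017-04-27,"Ekalakala","anomalure",1
"OBS_12",2017-05-26,"Ekalakala","anomalure",1
"OBS_13",2017-06-22,"Ekalakala","anomalure",1
"OBS_14",2017-06-26,"Ekalakala","anomalure",1
"OBS_15",2017-07-09,"Ekalakala","anomalure",1
"OBS_16",2017-08-10,"Ekalakala","anomalure",1
"OBS_17",2017-08-13,"Ekalakala","anomalure",1
"OBS_18",2017-08-17,"Ekalakala","anomalure",1
"OBS_19",2017-10-09,"Ekalakala","anomalure",1
"OBS_20",2017-11-08,"Ekalakala","anomalure",1
"OBS_21",2017-11-14,"Ekalakala","anomalure",1
"OBS_22",2017-11-28,"Ekalakala","anomalure",1
"OBS_23",2017-12-12,"Ekalakala","anomalure",1
"OBS_24",2018-01-08,"Ekalakala","anomalure",1
"OBS_25",2018-01-14,"Ekalakala","anomalure",1
"OBS_26",2018-01-19,"Ekalakala","anomalure",1
"OBS_27",2018-02-05,"Ekalakala","anomalure",1
"OBS_28",2018-02-07,"Ekalakala","anomalure",1
"OBS_29",2018-03-05,"Ekalakala","anomalure",1
"OBS_30",2018-03-20,"Ekalakala","anomalure",1
"OBS_31",2018-04-12,"Ekalakala","anomalure",1
"OBS_32",2018-05-04,"Ekalakala","duiker",1
"OBS_33",2018-06-10,"Ekalakala","squirrel",1
"OBS_34",2018-07-30,"Kokoalongo","anomalure",1
"OBS_35",2018-08-03,"Kokoalongo","anomalure",1
"OBS_36",2018-10-10,"Kokoalongo","anomalure",1
"OBS_37",2018-10-19,"Kokoalongo","duiker",1
"OBS_38",2018-11-21,"Kokoalongo","duiker",1
"OBS_39",2018-11-30,"Kokoalongo","duiker",1
"OBS_40",2018-12-22,"Kokoalongo","duiker",1
"OBS_41",2018-12-26,"Kokoalongo","duiker",1
"OBS_42",2019-01-06,"Kokoalongo","duiker",1
"OBS_43",2019-02-16,"Kokoalongo","duiker",1
"OBS_44",2019-02-17,"Kokoalongo","duiker",1
"OBS_45",2019-04-02,"Kokoalongo","duiker",1
"OBS_46",2019-04-10,"Kokoalongo","duiker",1
"OBS_47",2019-04-23,"Kokoalongo","duiker",1
"OBS_48",2019-05-14,"Kokoalongo","squirrel",1
"OBS_49",2019-06-19,"Kokoalongo","squirrel",1
"OBS_50",2019-07-05,"Kokoalongo","squirrel",1
"OBS_51",2019-09-02,"Kokoalongo","squirrel",1
"OBS_52",2019-09-03,"Kokoalongo","squirrel",1
"OBS_53",2019-09-08,"Kokoalongo","squirrel",1
"OBS_54",2019-09-19,"Kokoalongo","squirrel",1
"OBS_55",2019-10-09,"Kokoalongo","squirrel",1
"OBS_56",2019-11-13,"Kokoalongo","squirrel",1
"OBS_57",2019-11-24,"Kokoalongo","squirrel",1
"OBS_58",2019-12-05,"Kokoalongo","squirrel",1
"OBS_59",2020-01-22,"Kokoalongo","squirrel",1
"OBS_60",2019-07-31,"Ekalakala","anomalure",0
"OBS_61",2019-08-02,"Ekalakala","anomalure",0
"OBS_62",2019-08-14,"Ekalakala","anomalure",0
"OBS_63",2019-08-17,"Ekalakala","anomalure",0
"OBS_64",2019-09-11,"Ekalakala","duiker",0
"OBS_65",2019-09-21,"Ekalakala","duiker",0
"OBS_66",2019-09-25,"Kokoalongo","anomalure",0
"OBS_67",2019-10-10,"Kokoalongo","anomalure",0
"OBS_68",2019-10-26,"Kokoalongo","anomalure",0
"OBS_69",2019-11-22,"Kokoalongo","duiker",0
"OBS_70",2019-11-26,"Kokoalongo","duiker",0
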